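## Run configuration: one nested YAML document covering phantom
## parameters, architecture, loss weights, training hyperparameters,
## paths and the seed. Precedence is CLI flags > config file > defaults.

#' Default run configuration
#'
#' @return nested list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(
      n = 100L,
      negative_fraction = 0.3,
      image_size = 64L,
      nodule_count_range = c(1L, 4L),
      nodule_diameter_range = c(5, 11),
      vessel_count_range = c(2L, 5L),
      distractor_count_range = c(1L, 3L),
      noise_sigma = 0.03,
      parenchyma_intensity = 0.2,
      tissue_intensity = 0.55,
      lesion_intensity = 0.75,
      distractor_intensity = 0.85
    ),
    cascade = list(
      width_scale = 0.125,
      gating = "concat",
      threshold = 0.5,
      soft = TRUE,
      norm = TRUE
    ),
    loss = list(
      mu1 = 0.9, mu2 = 0.9, mu3 = 0.999,
      extractor = list(layer_index = 12L, width_scale = 0.125,
                       counting = "conv")
    ),
    training = list(
      learning_rate = 0.001,
      weight_decay = 1e-4,
      batch_size = 4L,
      epochs = 20L,
      val_fraction = 0.2,
      aux_loss_weight = 10
    ),
    logging = "info"
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' Unspecified fields fall back to [default_config()] values; the
#' representation round-trips losslessly.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  structure(merge_config(unclass(default_config()), user), class = "run_config")
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_phantom_params <- function(config) {
  p <- config$phantom
  phantom_params(
    image_size = p$image_size,
    nodule_count_range = unlist(p$nodule_count_range),
    nodule_diameter_range = unlist(p$nodule_diameter_range),
    vessel_count_range = unlist(p$vessel_count_range),
    distractor_count_range = unlist(p$distractor_count_range),
    noise_sigma = p$noise_sigma,
    parenchyma_intensity = p$parenchyma_intensity,
    tissue_intensity = p$tissue_intensity,
    lesion_intensity = p$lesion_intensity,
    distractor_intensity = p$distractor_intensity
  )
}

config_cascade <- function(config) {
  c <- config$cascade
  cascade_config(width_scale = c$width_scale, gating = c$gating,
                 threshold = c$threshold, soft = c$soft, norm = c$norm)
}

config_hyper <- function(config) {
  t <- config$training
  l <- config$loss
  default_hyperparameters(
    learning_rate = t$learning_rate,
    weight_decay = t$weight_decay,
    batch_size = t$batch_size,
    epochs = t$epochs,
    loss_weights = loss_weights(l$mu1, l$mu2, l$mu3),
    seed = config$seed
  )
}

config_extractor <- function(config) {
  e <- config$loss$extractor
  if (config$loss$mu2 <= 0) return(NULL)
  perceptual_extractor(layer_index = e$layer_index,
                       width_scale = e$width_scale,
                       seed = config$seed + 1L,
                       counting = e$counting %||% "conv")
}
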