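## The joint training loss and its three components: pixel-wise MSE,
## perceptual distance under a fixed VGG-19-style feature extractor, and
## a modified dice loss whose negative-sample branch penalises the L1
## magnitude of the prediction when the ground truth is empty.
##
## Each loss exists twice: an exported array-level function for analysis
## and testing, and an internal node-level op used during training.

#' Loss normalization coefficients
#'
#' @param mu1,mu2,mu3 non-negative weights of the pixel-wise, perceptual
#'   and dice components. Defaults follow the method's training setup.
#' @return object of class `"loss_weights"`.
#' @export
loss_weights <- function(mu1 = 0.9, mu2 = 0.9, mu3 = 0.999) {
  if (any(c(mu1, mu2, mu3) < 0)) stop("loss weights must be non-negative")
  structure(list(mu1 = mu1, mu2 = mu2, mu3 = mu3), class = "loss_weights")
}

as_map4 <- function(x) {
  if (is_ag_node(x)) return(x)
  ag_node(as_batched(x))
}

# ---- pixel-wise MSE -------------------------------------------------------

op_pixel_loss <- function(pred, gt) {
  pv <- ag_value(pred)
  diff <- pv - gt
  n <- length(diff)
  ag_op(sum(diff * diff) / n, list(pred),
        function(g) list(g * 2 * diff / n))
}

#' Pixel-wise mean-squared-error loss
#'
#' `L_pix = (1 / WH) * sum((pred - gt)^2)` over all pixels (averaged over
#' the batch when batched input is given).
#'
#' @param pred,gt numeric grids of identical dimensions.
#' @return non-negative scalar; zero iff `pred` equals `gt`.
#' @examples
#' pixel_loss(matrix(1, 2, 2), matrix(0, 2, 2)) # 1
#' @export
pixel_loss <- function(pred, gt) {
  if (!identical(dim(as_batched(pred)), dim(as_batched(gt)))) {
    stop("pixel_loss: dimension mismatch")
  }
  if (!all(is.finite(pred)) || !all(is.finite(gt))) {
    stop("pixel_loss: non-finite values")
  }
  as.numeric(ag_value(ag_no_grad(op_pixel_loss(as_map4(pred), as_batched(gt)))))
}

# ---- modified dice loss ---------------------------------------------------

op_dice_loss <- function(pred, gt) {
  pv <- ag_value(pred)
  d <- dim(pv)
  N <- d[4]
  npix <- d[1] * d[2] * d[3]
  pm <- matrix(pv, npix, N)
  gm <- matrix(gt, npix, N)
  sg <- .colSums(gm, npix, N)
  sp <- .colSums(pm, npix, N)
  si <- .colSums(pm * gm, npix, N)
  pos <- sg > 0
  vals <- ifelse(pos, 1 - 2 * si / (sp + sg), .colSums(abs(pm), npix, N) / npix)
  ag_op(mean(vals), list(pred), function(g) {
    dpm <- matrix(0, npix, N)
    for (n in seq_len(N)) {
      if (pos[n]) {
        S <- sp[n] + sg[n]
        dpm[, n] <- -2 * (gm[, n] * S - si[n]) / (S * S)
      } else {
        dpm[, n] <- sign(pm[, n]) / npix
      }
    }
    list(g * array(dpm / N, dim = d))
  })
}

#' Modified dice loss with a negative-sample branch
#'
#' For non-empty ground truth, the soft dice loss
#' `1 - 2 * sum(pred * gt) / (sum(pred) + sum(gt))`; for an all-zero
#' ground truth, the pixel-count-normalized L1 magnitude of the
#' prediction (so empty predictions on negative samples cost nothing).
#' On binary inputs the soft form coincides with the set-count dice.
#' Batched input is averaged per sample.
#'
#' @param pred real grid in `[0, 1]`.
#' @param gt binary grid (values in \{0, 1\}) of the same dimensions.
#' @return scalar in `[0, 1]`.
#' @examples
#' dice_loss(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 1, 0, 0), 2)) # 0
#' @export
dice_loss <- function(pred, gt) {
  if (!identical(dim(as_batched(pred)), dim(as_batched(gt)))) {
    stop("dice_loss: dimension mismatch")
  }
  if (!all(gt %in% c(0, 1))) {
    stop("dice_loss: ground truth must be binary (values in {0, 1})")
  }
  as.numeric(ag_value(ag_no_grad(op_dice_loss(as_map4(pred), as_batched(gt)))))
}

# ---- perceptual loss ------------------------------------------------------

#' Fixed VGG-19-style perceptual feature extractor
#'
#' The VGG-19 convolutional topology (conv blocks of widths
#' 64-64 / 128-128 / 256x4 / 512x4 / 512x4 with 2x2 max pooling between
#' blocks, ReLU after every convolution, no normalization), truncated at
#' the `layer_index`-th convolution. Weights are drawn once from a
#' seeded He-normal initialization and then held fixed: the extractor is
#' never trained, and identical inputs always give identical features.
#' Grayscale inputs are replicated to three channels.
#'
#' `width_scale` shrinks every block width proportionally (minimum 4
#' channels) so that desk-scale experiments stay cheap; `counting`
#' selects whether `layer_index` counts convolutional layers only or
#' convolution and pooling layers together.
#'
#' @param layer_index index of the tap layer (default 12).
#' @param width_scale multiplier on the block widths in (0, 1].
#' @param seed RNG seed for the fixed weights.
#' @param counting `"conv"` (count convolutions only) or `"all"` (count
#'   pooling layers too).
#' @return object of class `"perceptual_extractor"`.
#' @export
perceptual_extractor <- function(layer_index = 12L, width_scale = 1,
                                 seed = 99L, counting = c("conv", "all")) {
  counting <- match.arg(counting)
  stopifnot(layer_index >= 1, width_scale > 0, width_scale <= 1)
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  widths <- lapply(blocks, function(b) pmax(4L, as.integer(round(b * width_scale))))
  # flatten into a layer program: conv widths with pool markers between blocks
  program <- list()
  for (bi in seq_along(widths)) {
    for (w in widths[[bi]]) program[[length(program) + 1L]] <- w
    if (bi < length(widths)) program[[length(program) + 1L]] <- "pool"
  }
  # truncate at the tap
  count <- 0L
  keep <- 0L
  for (li in seq_along(program)) {
    is_conv <- is.numeric(program[[li]])
    if (counting == "conv") {
      if (is_conv) count <- count + 1L
    } else {
      count <- count + 1L
    }
    if (is_conv && count == layer_index) { keep <- li; break }
    if (!is_conv && counting == "all" && count == layer_index) { keep <- li; break }
  }
  if (keep == 0L) stop("layer_index ", layer_index, " exceeds the topology")
  program <- program[seq_len(keep)]

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  layers <- list()
  in_ch <- 3L
  for (p in program) {
    if (identical(p, "pool")) {
      layers[[length(layers) + 1L]] <- "pool"
    } else {
      w <- init_weight(c(3L, 3L, in_ch, p), 9 * in_ch)
      w$requires_grad <- FALSE # fixed features; gradients still flow through
      b <- init_const(p, 0)
      b$requires_grad <- FALSE
      layers[[length(layers) + 1L]] <- list(w = w, b = b)
      in_ch <- p
    }
  }
  # variance calibration: rescale each layer's weights so its post-ReLU
  # activations on seeded white noise have unit standard deviation. A
  # deep random ReLU stack otherwise amplifies both features and
  # gradients multiplicatively, which would let the perceptual term
  # drown the task losses.
  z <- ag_node(array(stats::rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  for (l in layers) {
    if (identical(l, "pool")) {
      z <- ag_no_grad(op_maxpool(z))
    } else {
      z <- ag_no_grad(op_relu(op_conv(z, l$w, l$b, pad = c(1L, 1L))))
      s <- stats::sd(ag_value(z))
      if (s > 0) {
        l$w$value <- l$w$value / s
        z$value <- z$value / s
      }
    }
  }
  # scale the tap layer so one pixel's feature vector has unit expected
  # norm: the loss normalizes by W_i * H_i only, and without this the
  # channel sum would grow the term (and its gradient) linearly in C_i
  last <- length(layers)
  while (identical(layers[[last]], "pool")) last <- last - 1L
  layers[[last]]$w$value <- layers[[last]]$w$value / sqrt(in_ch)
  structure(list(layers = layers, layer_index = as.integer(layer_index),
                 width_scale = width_scale, seed = as.integer(seed),
                 counting = counting, out_channels = in_ch),
            class = "perceptual_extractor")
}

# forward an (H, W, 1, N) node through the extractor; returns the tap
# feature node
extractor_forward <- function(extractor, x) {
  z <- op_concat(list(x, x, x))
  for (l in extractor$layers) {
    if (identical(l, "pool")) {
      z <- op_maxpool(z)
    } else {
      z <- op_relu(op_conv(z, l$w, l$b, pad = c(1L, 1L)))
    }
  }
  z
}

#' Extract the fixed perceptual features of a grid
#'
#' @param extractor a [perceptual_extractor()].
#' @param x numeric grid (H, W) or batched array.
#' @return feature array (H_i, W_i, C_i\[, N\]).
#' @export
perceptual_features <- function(extractor, x) {
  had_batch <- length(dim(x)) == 4
  out <- ag_no_grad(extractor_forward(extractor, ag_node(as_batched(x))))
  unbatch(ag_value(out), had_batch)
}

op_feature_mse <- function(fa, fb) {
  av <- ag_value(fa); bv <- ag_value(fb)
  d <- dim(av)
  norm <- d[1] * d[2] * d[4] # W_i * H_i per sample, averaged over batch
  diff <- av - bv
  ag_op(sum(diff * diff) / norm, list(fa, fb), function(g) {
    list(if (needs_grad(fa)) g * 2 * diff / norm,
         if (needs_grad(fb)) g * (-2) * diff / norm)
  })
}

op_perceptual_loss <- function(pred, gt_node, extractor) {
  op_feature_mse(extractor_forward(extractor, pred),
                 extractor_forward(extractor, gt_node))
}

#' Perceptual loss under a fixed feature extractor
#'
#' Squared Euclidean distance between the tap-layer features of `pred`
#' and `gt`, normalized by the tap layer's spatial size `W_i * H_i`.
#' Symmetric in its arguments and zero iff the features coincide.
#'
#' @param pred,gt numeric grids of identical dimensions.
#' @param extractor a [perceptual_extractor()].
#' @return non-negative scalar.
#' @export
perceptual_loss <- function(pred, gt, extractor) {
  stopifnot(inherits(extractor, "perceptual_extractor"))
  if (!identical(dim(as_batched(pred)), dim(as_batched(gt)))) {
    stop("perceptual_loss: dimension mismatch")
  }
  as.numeric(ag_value(ag_no_grad(
    op_perceptual_loss(as_map4(pred), ag_node(as_batched(gt)), extractor)
  )))
}

# ---- joint loss -----------------------------------------------------------

op_joint_loss <- function(pred, gt, weights, extractor) {
  parts <- list(pix = op_pixel_loss(pred, gt))
  w <- c(weights$mu1)
  if (weights$mu2 > 0 && !is.null(extractor)) {
    parts$perc <- op_perceptual_loss(pred, ag_node(gt), extractor)
    w <- c(w, weights$mu2)
  }
  parts$dice <- op_dice_loss(pred, gt)
  w <- c(w, weights$mu3)
  total <- op_scalar_wsum(unname(parts), w)
  attr(total, "components") <- vapply(parts, function(p) as.numeric(ag_value(p)),
                                      numeric(1))
  total
}

#' Joint training loss
#'
#' `L_j = mu1 * L_pix + mu2 * L_perc + mu3 * L_d`.
#'
#' @param pred real grid in `[0, 1]`.
#' @param gt binary ground-truth grid.
#' @param weights a [loss_weights()].
#' @param extractor a [perceptual_extractor()]; may be `NULL` when
#'   `mu2 = 0`.
#' @return scalar with attribute `"components"` holding the unweighted
#'   component values.
#' @export
joint_loss <- function(pred, gt, weights = loss_weights(), extractor = NULL) {
  stopifnot(inherits(weights, "loss_weights"))
  if (weights$mu2 > 0 && is.null(extractor)) {
    stop("joint_loss: an extractor is required when mu2 > 0")
  }
  if (!all(gt %in% c(0, 1))) {
    stop("joint_loss: ground truth must be binary")
  }
  node <- ag_no_grad(op_joint_loss(as_map4(pred), as_batched(gt), weights,
                                   extractor))
  structure(as.numeric(ag_value(node)), components = attr(node, "components"))
}
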