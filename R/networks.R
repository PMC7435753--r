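## The three cascaded sub-networks and the stage-to-stage gating.
##
## Stage 1 segments the lung parenchyma (inception stem + dense skip
## connections), stage 2 detects nodule candidates on the
## parenchyma-gated image (dilated convolution blocks), stage 3 decides
## true nodules on the candidate-gated input (multi-resolution blocks +
## multi-scale pooling). All three map an H x W input (divisible by 8)
## to an H x W probability map through a 1x1 convolution + sigmoid head.

round4 <- function(x) max(4L, 4L * as.integer(round(x / 4)))

#' Cascade architecture configuration
#'
#' Channel widths follow the reference architecture (stem 64; encoder
#' 128/256/512; candidate stages 64/128/256/512; determination base 32)
#' scaled by `width_scale` and rounded to multiples of four.
#'
#' @param width_scale multiplier on all channel widths in (0, 1].
#' @param gating stage-3 input mode: `"concat"` stacks the gated image
#'   with the candidate probability map (2 channels); `"multiply"` uses
#'   the gated image alone.
#' @param threshold binarization threshold in (0, 1) for hard gating at
#'   inference.
#' @param soft use soft (differentiable) gating during training.
#' @param norm batch normalization after every convolution.
#' @param det_base base width of the determination sub-network
#'   (default: 32 scaled by `width_scale`). The determination stage does
#'   the hardest discrimination (nodule vs vessel shape), so it can be
#'   widened independently of the segmentation stages.
#' @return object of class `"cascade_config"`.
#' @export
cascade_config <- function(width_scale = 1, gating = c("concat", "multiply"),
                           threshold = 0.5, soft = TRUE, norm = TRUE,
                           det_base = NULL) {
  gating <- match.arg(gating)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (width_scale <= 0 || width_scale > 1) stop("width_scale must be in (0, 1]")
  det_base <- if (is.null(det_base)) round4(32 * width_scale)
              else round4(det_base)
  structure(list(
    width_scale = width_scale,
    par_stem = round4(64 * width_scale),
    par_enc = vapply(c(128, 256, 512) * width_scale, round4, integer(1)),
    cand = vapply(c(64, 128, 256, 512) * width_scale, round4, integer(1)),
    det_base = det_base,
    gating = gating, threshold = threshold, soft = soft, norm = norm
  ), class = "cascade_config")
}

#' Build the parenchyma segmentation sub-network
#'
#' Inception stem at full resolution, three stride-2 encoder
#' convolutions each fed with the dense concatenation of all earlier
#' features resampled to its input resolution, a mirrored decoder of
#' three transposed convolutions (again densely fed), one full-resolution
#' refinement convolution, and a 1x1 + sigmoid head.
#'
#' @param config a [cascade_config()].
#' @return a network module; input spatial dims must be divisible by 8.
#' @export
build_parenchyma_net <- function(config = cascade_config()) {
  m <- new_module("parenchyma_net")
  s <- config$par_stem; e <- config$par_enc; nm <- config$norm
  m$children <- list(
    stem = inception_block(1L, "segmentation", out_ch = s,
                           branch_ch = max(4L, s %/% 4L), norm = nm),
    enc1 = conv_unit(s, e[1], stride = c(2, 2), norm = nm),
    enc2 = conv_unit(s + e[1], e[2], stride = c(2, 2), norm = nm),
    enc3 = conv_unit(s + e[1] + e[2], e[3], stride = c(2, 2), norm = nm),
    dec1 = conv_unit(s + e[1] + e[2] + e[3], e[3], stride = c(2, 2),
                     transposed = TRUE, norm = nm),
    dec2 = conv_unit(s + e[1] + e[2] + e[3], e[2], stride = c(2, 2),
                     transposed = TRUE, norm = nm),
    dec3 = conv_unit(s + e[1] + e[2], e[1], stride = c(2, 2),
                     transposed = TRUE, norm = nm),
    refine = conv_unit(s + e[1], s, norm = nm),
    head = conv_unit(s, 1L, k = c(1, 1), activation = "sigmoid", norm = FALSE,
                     bias_init = -2)
  )
  m$forward <- function(x, training = TRUE) {
    d <- dim(ag_value(x))
    if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
      stop("input spatial dims must be divisible by 8, got ", d[1], "x", d[2])
    }
    ch <- m$children
    x0 <- ch$stem$forward(x, training)                               # full
    x1 <- ch$enc1$forward(x0, training)                              # /2
    x2 <- ch$enc2$forward(op_dense_concat(list(x0, x1), 2L), training)   # /4
    x3 <- ch$enc3$forward(op_dense_concat(list(x0, x1, x2), 3L), training) # /8
    z3 <- op_dense_concat(list(x0, x1, x2, x3), 4L)                  # /8
    d1 <- ch$dec1$forward(z3, training)                              # /4
    d2 <- ch$dec2$forward(op_dense_concat(list(x0, x1, x2, d1), 4L), training) # /2
    d3 <- ch$dec3$forward(op_dense_concat(list(x0, x1, d2), 3L), training)     # full
    r <- ch$refine$forward(op_dense_concat(list(x0, d3), 2L), training)
    ch$head$forward(r, training)
  }
  m
}

#' Build the nodule-candidate detection sub-network
#'
#' A U-Net-like topology in which every encoder stage is a
#' [dilated_conv_block()] (stride 1 at full resolution, then three
#' stride-2 stages) and every decoder stage a [dilated_deconv_block()],
#' with a full-resolution refinement convolution and a 1x1 + sigmoid
#' head. Every convolution stage uses dilation rate 2.
#'
#' @param config a [cascade_config()].
#' @export
build_candidate_net <- function(config = cascade_config()) {
  m <- new_module("candidate_net")
  w <- config$cand; nm <- config$norm
  m$children <- list(
    e1 = dilated_conv_block(1L, w[1], stride = 1L, norm = nm),
    e2 = dilated_conv_block(w[1], w[2], stride = 2L, norm = nm),
    e3 = dilated_conv_block(w[2], w[3], stride = 2L, norm = nm),
    e4 = dilated_conv_block(w[3], w[4], stride = 2L, norm = nm),
    d1 = dilated_deconv_block(w[4], w[3], w[3], norm = nm),
    d2 = dilated_deconv_block(w[3], w[2], w[2], norm = nm),
    d3 = dilated_deconv_block(w[2], w[1], w[1], norm = nm),
    refine = conv_unit(w[1], w[1], dil = c(2, 2), norm = nm),
    head = conv_unit(w[1], 1L, k = c(1, 1), activation = "sigmoid", norm = FALSE,
                     bias_init = -2)
  )
  m$forward <- function(x, training = TRUE) {
    d <- dim(ag_value(x))
    if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
      stop("input spatial dims must be divisible by 8, got ", d[1], "x", d[2])
    }
    ch <- m$children
    f1 <- ch$e1$forward(x, training)          # full
    f2 <- ch$e2$forward(f1, training)         # /2
    f3 <- ch$e3$forward(f2, training)         # /4
    f4 <- ch$e4$forward(f3, training)         # /8
    u1 <- ch$d1$forward(f4, f3, training)     # /4
    u2 <- ch$d2$forward(u1, f2, training)     # /2
    u3 <- ch$d3$forward(u2, f1, training)     # full
    ch$head$forward(ch$refine$forward(u3, training), training)
  }
  m
}

#' Build the nodule determination sub-network
#'
#' Encoder alternating [multires_block()] (channels triple) and
#' [multiscale_pool_block()] (spatial dims halve, channels conserved),
#' two levels deep; decoder of mirrored transposed convolutions back to
#' input resolution; 1x1 + sigmoid head.
#'
#' @param config a [cascade_config()].
#' @param in_ch input channels (2 for the default concat gating).
#' @export
build_determination_net <- function(config = cascade_config(), in_ch = 2L) {
  m <- new_module("determination_net")
  b <- config$det_base; nm <- config$norm
  m$children <- list(
    stem = conv_unit(in_ch, b, norm = nm),
    mr1 = multires_block(b, norm = nm),        # 3b, full
    mp1 = multiscale_pool_block(3L * b, norm = nm), # 3b, /2
    mr2 = multires_block(3L * b, norm = nm),   # 9b, /2
    mp2 = multiscale_pool_block(9L * b, norm = nm), # 9b, /4
    up1 = conv_unit(9L * b, 3L * b, stride = c(2, 2), transposed = TRUE,
                    norm = nm),                # /2
    c1 = conv_unit(3L * b, 3L * b, norm = nm),
    up2 = conv_unit(3L * b, b, stride = c(2, 2), transposed = TRUE, norm = nm),
    c2 = conv_unit(b, b, norm = nm),
    head = conv_unit(b, 1L, k = c(1, 1), activation = "sigmoid", norm = FALSE,
                     bias_init = -2)
  )
  m$forward <- function(x, training = TRUE) {
    d <- dim(ag_value(x))
    if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
      stop("input spatial dims must be divisible by 8, got ", d[1], "x", d[2])
    }
    ch <- m$children
    z <- ch$stem$forward(x, training)
    z <- ch$mp1$forward(ch$mr1$forward(z, training), training)
    z <- ch$mp2$forward(ch$mr2$forward(z, training), training)
    z <- ch$c1$forward(ch$up1$forward(z, training), training)
    z <- ch$c2$forward(ch$up2$forward(z, training), training)
    ch$head$forward(z, training)
  }
  m
}

# gate factor for one probability map: "soft" = the map itself,
# "hard" = constant thresholded mask (inference), "st" = hard mask with
# a straight-through gradient (late-stage training)
gate_factor <- function(prob, kind, threshold) {
  switch(kind,
         soft = prob,
         hard = ag_node((ag_value(prob) >= threshold) * 1),
         st = op_hard_gate_st(prob, threshold),
         stop("unknown gate kind: ", kind))
}

# node-level stage gate
op_stage_gate <- function(image, prob, mode, kind, threshold) {
  gated <- op_mul(image, gate_factor(prob, kind, threshold))
  if (mode == "concat") op_concat(list(gated, prob)) else gated
}

#' Gate a stage input with the previous stage's probability map
#'
#' In `"multiply"` mode the image is multiplied element-wise with the
#' gate — the probability map itself when `soft`, its hard thresholding
#' otherwise. In `"concat"` mode the gated image is stacked with the
#' (un-thresholded) probability map as a 2-channel input.
#'
#' @param image numeric grid (H, W) or batched array.
#' @param prob probability grid of the same spatial dims.
#' @param mode `"multiply"` or `"concat"`.
#' @param soft differentiable soft gating (training) vs hard
#'   thresholding (inference).
#' @param threshold hard-gate threshold in (0, 1).
#' @return the gated input array.
#' @export
apply_stage_gate <- function(image, prob, mode = c("multiply", "concat"),
                             soft = FALSE, threshold = 0.5) {
  mode <- match.arg(mode)
  bi <- as_batched(image); bp <- as_batched(prob)
  if (!identical(dim(bi)[c(1, 2, 4)], dim(bp)[c(1, 2, 4)])) {
    stop("apply_stage_gate: dimension mismatch")
  }
  had_batch <- length(dim(image)) == 4
  out <- ag_no_grad(op_stage_gate(ag_node(bi), ag_node(bp), mode,
                                  if (soft) "soft" else "hard", threshold))
  res <- unbatch(ag_value(out), had_batch)
  # a plain-matrix input gets a plain matrix back in multiply mode
  if (is.null(dim(image)) || length(dim(image)) == 2) {
    if (dim(res)[3] == 1L) res <- matrix(res, dim(res)[1], dim(res)[2])
  }
  res
}

#' Build the full three-stage cascade
#'
#' Weights are initialized from R's RNG: call `set.seed()` first (or use
#' [train_cascade()], which seeds everything) for a reproducible
#' network.
#'
#' @param config a [cascade_config()].
#' @return object of class `"nodule_cascade"`.
#' @export
build_cascade <- function(config = cascade_config()) {
  det_in <- if (config$gating == "concat") 2L else 1L
  structure(list(
    parenchyma = build_parenchyma_net(config),
    candidate = build_candidate_net(config),
    determination = build_determination_net(config, in_ch = det_in),
    config = config
  ), class = "nodule_cascade")
}

#' @export
print.nodule_cascade <- function(x, ...) {
  cat("<nodule_cascade>\n")
  cat(sprintf("  parenchyma net:    %8d parameters\n", count_params(x$parenchyma)))
  cat(sprintf("  candidate net:     %8d parameters\n", count_params(x$candidate)))
  cat(sprintf("  determination net: %8d parameters\n", count_params(x$determination)))
  cat(sprintf("  gating: %s (threshold %.2f), width scale %.3g\n",
              x$config$gating, x$config$threshold, x$config$width_scale))
  invisible(x)
}

# full forward pass on a node; returns the three probability nodes.
# gate: "soft" (early training), "st" (straight-through hard gates,
# late training), "hard" (inference).
cascade_forward_nodes <- function(cascade, x, training = TRUE, gate = NULL) {
  cfg <- cascade$config
  if (is.null(gate)) {
    gate <- if (!training) "hard" else if (cfg$soft) "soft" else "st"
  }
  p1 <- cascade$parenchyma$forward(x, training)
  g1 <- op_mul(x, gate_factor(p1, gate, cfg$threshold))
  p2 <- cascade$candidate$forward(g1, training)
  x3 <- op_stage_gate(g1, p2, cfg$gating, gate, cfg$threshold)
  p3 <- cascade$determination$forward(x3, training)
  list(parenchyma = p1, candidate = p2, nodule = p3)
}

#' Run the cascade on an image
#'
#' Stage 1 sees the raw image; stage 2 the parenchyma-gated image;
#' stage 3 the candidate-gated input. At inference (the default) gating
#' is hard at the configured threshold.
#'
#' @param cascade a [build_cascade()] network.
#' @param image numeric matrix (H, W), an [image_slice()], or a batched
#'   (H, W, 1, N) array; spatial dims divisible by 8.
#' @param soft override the soft/hard gating choice.
#' @return object of class `"cascade_output"`: list of
#'   `parenchyma_prob`, `candidate_prob` and `nodule_prob` grids, all in
#'   `[0, 1]` at the input's resolution.
#' @export
cascade_forward <- function(cascade, image, soft = FALSE) {
  stopifnot(inherits(cascade, "nodule_cascade"))
  if (inherits(image, "image_slice")) image <- image$values
  had_batch <- length(dim(image)) == 4
  x <- ag_node(as_batched(image))
  out <- ag_no_grad(cascade_forward_nodes(cascade, x, training = FALSE,
                                          gate = if (soft) "soft" else "hard"))
  structure(list(
    parenchyma_prob = unbatch(ag_value(out$parenchyma), had_batch),
    candidate_prob = unbatch(ag_value(out$candidate), had_batch),
    nodule_prob = unbatch(ag_value(out$nodule), had_batch)
  ), class = "cascade_output")
}

#' @export
print.cascade_output <- function(x, ...) {
  d <- dim(x$nodule_prob)
  cat("<cascade_output> three", paste(d[1], "x", d[2]),
      "probability maps (parenchyma, candidate, nodule)\n")
  cat(sprintf("  nodule map: %.1f%% of pixels above 0.5\n",
              100 * mean(x$nodule_prob >= 0.5)))
  invisible(x)
}

#' Save / load cascade weights
#'
#' The checkpoint holds the configuration, every parameter value and the
#' batch-norm running statistics; [load_cascade()] rebuilds the network
#' and restores them.
#'
#' @param cascade a `nodule_cascade`.
#' @param path checkpoint file path (RDS).
#' @export
save_cascade <- function(cascade, path) {
  saveRDS(list(config = cascade$config,
               state = module_state(unclass(cascade)[1:3])), path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  ck <- readRDS(path)
  cascade <- build_cascade(ck$config)
  module_load_state(unclass(cascade)[1:3], ck$state)
  cascade
}
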