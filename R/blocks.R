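## Network building blocks: the dilated-convolution size algebra, the
## factorized inception module, dense skip connections with power-of-two
## resampling, dilated convolution / de-convolution blocks, the
## multi-resolution convolution block and the multi-scale pooling block.
##
## User-facing feature maps are (H, W, C) or (H, W, C, N) numeric arrays;
## a missing batch axis is treated as N = 1.

#' Effective kernel size of a dilated convolution
#'
#' A kernel of size `k` with dilation rate `d` has taps spaced `d` pixels
#' apart and therefore covers `n = k + (k - 1)(d - 1)` input pixels.
#'
#' @param k kernel size (>= 1).
#' @param d dilation rate (>= 1); `d = 1` is a standard convolution.
#' @return integer effective size `n`.
#' @examples
#' effective_kernel_size(3, 2) # 5
#' @export
effective_kernel_size <- function(k, d) {
  if (any(k < 1) || any(d < 1)) stop("k and d must be positive")
  as.integer(k + (k - 1) * (d - 1))
}

#' Declarative description of one convolution
#'
#' @param kernel kernel size, scalar or (rows, cols).
#' @param in_channels,out_channels channel counts.
#' @param stride stride, scalar or per-axis.
#' @param dilation dilation rate (>= 1).
#' @param padding zero-padding, scalar or per-axis.
#' @param transposed fractional-stride (transposed) mode.
#' @return an object of class `"block_spec"`.
#' @export
block_spec <- function(kernel = 3, in_channels = 1, out_channels = 1,
                       stride = 1, dilation = 1, padding = 0,
                       transposed = FALSE) {
  kernel <- as.integer(rep(kernel, length.out = 2))
  stride <- as.integer(rep(stride, length.out = 2))
  padding <- as.integer(rep(padding, length.out = 2))
  dilation <- as.integer(dilation)
  if (any(kernel < 1) || dilation < 1 || any(stride < 1) ||
      any(padding < 0) || in_channels < 1 || out_channels < 1) {
    stop("invalid block_spec")
  }
  structure(list(kernel = kernel, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels), stride = stride,
                 dilation = dilation, padding = padding,
                 transposed = isTRUE(transposed)),
            class = "block_spec")
}

#' Spatial output size of a (dilated) convolution
#'
#' `o = floor((i + 2p - n) / s) + 1` with `n` the effective kernel size.
#'
#' @param i input size (pixels, one axis).
#' @param k kernel size, or a [block_spec()] (then `d`, `s`, `p` are taken
#'   from it, per axis, and `o` is returned per axis).
#' @param d dilation rate.
#' @param s stride.
#' @param p zero-padding.
#' @return integer output size (>= 1), or an error if the effective
#'   kernel exceeds the padded input.
#' @examples
#' conv_output_size(8, k = 3, d = 2, p = 0) # 4
#' conv_output_size(8, k = 3, d = 2, p = 2) # 8
#' @export
conv_output_size <- function(i, k, d = 1, s = 1, p = 0) {
  if (inherits(k, "block_spec")) {
    spec <- k
    return(vapply(1:2, function(ax) {
      conv_output_size(i[min(ax, length(i))], spec$kernel[ax], spec$dilation,
                       spec$stride[ax], spec$padding[ax])
    }, integer(1)))
  }
  n <- effective_kernel_size(k, d)
  if (i + 2 * p < n) stop("effective kernel (", n, ") exceeds padded input")
  as.integer((i + 2 * p - n) %/% s + 1L)
}

as_batched <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) {
    x <- array(x, dim = c(dim(as.matrix(x)), 1L, 1L))
  } else if (length(d) == 3) {
    dim(x) <- c(d, 1L)
  }
  x
}

unbatch <- function(x, had_batch) {
  if (!had_batch) {
    d <- dim(x)
    dim(x) <- d[1:3]
  }
  x
}

#' Run a block (or network module) forward on a feature-map array
#'
#' @param block a module built by one of the `*_block()` constructors.
#' @param x numeric array (H, W, C) or (H, W, C, N).
#' @param ... further feature-map arguments (e.g. the skip input of
#'   [dilated_deconv_block()]).
#' @param training use batch statistics in normalization layers.
#' @return a numeric array of the same batch arity as `x`.
#' @export
block_forward <- function(block, x, ..., training = FALSE) {
  stopifnot(inherits(block, "nc_module"))
  had_batch <- length(dim(x)) == 4
  extra <- lapply(list(...), function(e) ag_node(as_batched(e)))
  args <- c(list(ag_node(as_batched(x))), extra,
            list(training = training))
  out <- ag_no_grad(do.call(block$forward, args))
  unbatch(ag_value(out), had_batch)
}

#' Factorized inception module
#'
#' Three parallel branches — a 1x1 bottleneck, a bottleneck followed by
#' one factorized 1x3/3x1 pair, and a bottleneck followed by two stacked
#' pairs — concatenated and projected by a trailing 1x1 convolution.
#' The segmentation variant (first layer of the parenchyma network) has
#' fixed-width branches and projects to `out_ch` (default 64); the
#' candidate variant uses half-width branches and projects back to the
#' input width, preserving the channel count.
#'
#' @param in_ch input channels.
#' @param variant `"segmentation"` or `"candidate"`.
#' @param out_ch projection width for the segmentation variant.
#' @param branch_ch branch width for the segmentation variant.
#' @param norm batch normalization flag, passed to every convolution.
#' @return a module; forward maps (H, W, in_ch, N) to (H, W, out, N)
#'   preserving spatial size.
#' @export
inception_block <- function(in_ch, variant = c("segmentation", "candidate"),
                            out_ch = 64L, branch_ch = 16L, norm = TRUE) {
  variant <- match.arg(variant)
  m <- new_module("inception")
  if (variant == "candidate") {
    branch_ch <- max(1L, in_ch %/% 2L)
    out_ch <- in_ch
  }
  u <- function(ic, oc, k) conv_unit(ic, oc, k = k, norm = norm)
  m$children <- list(
    b1 = list(u(in_ch, branch_ch, c(1, 1))),
    b2 = list(u(in_ch, branch_ch, c(1, 1)),
              u(branch_ch, branch_ch, c(1, 3)),
              u(branch_ch, branch_ch, c(3, 1))),
    b3 = list(u(in_ch, branch_ch, c(1, 1)),
              u(branch_ch, branch_ch, c(1, 3)),
              u(branch_ch, branch_ch, c(3, 1)),
              u(branch_ch, branch_ch, c(1, 3)),
              u(branch_ch, branch_ch, c(3, 1))),
    proj = list(u(3L * branch_ch, out_ch, c(1, 1)))
  )
  m$out_ch <- out_ch
  m$forward <- function(x, training = TRUE) {
    run <- function(layers, z) {
      for (l in layers) z <- l$forward(z, training)
      z
    }
    cat3 <- op_concat(list(run(m$children$b1, x),
                           run(m$children$b2, x),
                           run(m$children$b3, x)))
    run(m$children$proj, cat3)
  }
  m
}

# resampling factor between two power-of-two related sizes
pow2_factor <- function(from, to) {
  if (from == to) return(1L)
  r <- max(from, to) / min(from, to)
  f <- as.integer(round(r))
  if (f < 1 || bitwAnd(f, f - 1L) != 0L || f != r) {
    stop("resolution ratio ", r, " is not a power of two")
  }
  f
}

# node-level dense concatenation: every feature resampled to the target
# feature's resolution (average pooling down, nearest-neighbour up),
# then channel-concatenated in order.
op_dense_concat <- function(features, target_index) {
  target_d <- dim(ag_value(features[[target_index]]))
  resampled <- lapply(features, function(f) {
    d <- dim(ag_value(f))
    fh <- pow2_factor(d[1], target_d[1])
    fw <- pow2_factor(d[2], target_d[2])
    if (d[1] > target_d[1]) {
      op_avgpool(f, c(fh, fw))
    } else if (d[1] < target_d[1]) {
      op_upsample(f, c(fh, fw))
    } else {
      f
    }
  })
  if (length(resampled) == 1L) return(resampled[[1L]])
  op_concat(resampled)
}

#' Dense skip concatenation with power-of-two resampling
#'
#' Resamples every feature map in `features` to the spatial resolution of
#' `features[[target_index]]` — average pooling when coming down from a
#' finer resolution, nearest-neighbour upsampling when coming up — and
#' concatenates all of them along the channel axis, in list order. Output
#' channels are the sum of input channels. Non-power-of-two resolution
#' ratios are rejected.
#'
#' @param features list of (H_j, W_j, C_j) or batched arrays, ordered
#'   from shallowest.
#' @param target_index index of the feature defining the target
#'   resolution.
#' @return the concatenated array at the target resolution.
#' @export
dense_resample_concat <- function(features, target_index) {
  stopifnot(length(features) >= 1,
            target_index >= 1, target_index <= length(features))
  had_batch <- length(dim(features[[1]])) == 4
  nodes <- lapply(features, function(f) ag_node(as_batched(f)))
  out <- ag_no_grad(op_dense_concat(nodes, target_index))
  unbatch(ag_value(out), had_batch)
}

#' Dilated convolution block
#'
#' Inception module (candidate variant, channel-preserving) followed by
#' one 3x3 dilation-2 convolution mapping to `out_ch`. With "same"
#' padding and stride 1 the spatial size is preserved; the trailing
#' convolution carries the block's stride when used for downsampling.
#' Each block grows the receptive field by 4 (effective kernel 5).
#'
#' @param in_ch,out_ch channel counts.
#' @param stride stride of the trailing dilated convolution.
#' @param norm batch normalization flag.
#' @export
dilated_conv_block <- function(in_ch, out_ch, stride = 1L, norm = TRUE) {
  m <- new_module("dilated_conv_block")
  m$children <- list(
    inc = inception_block(in_ch, "candidate", norm = norm),
    dconv = conv_unit(in_ch, out_ch, k = c(3, 3), stride = stride,
                      dil = c(2, 2), norm = norm)
  )
  m$forward <- function(x, training = TRUE) {
    z <- m$children$inc$forward(x, training)
    m$children$dconv$forward(z, training)
  }
  m
}

#' Dilated de-convolution block
#'
#' Transposed convolution (stride 2, spatial size doubles), channel
#' concatenation with the mirrored encoder feature, then two successive
#' 3x3 dilation-2 convolutions.
#'
#' @param in_ch decoder input channels.
#' @param skip_ch channels of the encoder skip feature.
#' @param out_ch output channels.
#' @param norm batch normalization flag.
#' @export
dilated_deconv_block <- function(in_ch, skip_ch, out_ch, norm = TRUE) {
  m <- new_module("dilated_deconv_block")
  m$children <- list(
    up = conv_unit(in_ch, out_ch, k = c(3, 3), stride = c(2, 2),
                   transposed = TRUE, norm = norm),
    c1 = conv_unit(out_ch + skip_ch, out_ch, k = c(3, 3), dil = c(2, 2),
                   norm = norm),
    c2 = conv_unit(out_ch, out_ch, k = c(3, 3), dil = c(2, 2), norm = norm)
  )
  m$forward <- function(x, skip, training = TRUE) {
    u <- m$children$up$forward(x, training)
    du <- dim(ag_value(u)); ds <- dim(ag_value(skip))
    if (du[1] != ds[1] || du[2] != ds[2]) {
      stop("skip/decoder spatial mismatch: ", du[1], "x", du[2], " vs ",
           ds[1], "x", ds[2])
    }
    z <- op_concat(list(u, skip))
    z <- m$children$c1$forward(z, training)
    m$children$c2$forward(z, training)
  }
  m
}

#' Multi-resolution convolution block
#'
#' Three parallel routes: full resolution (3x3, stride (1,1), `c`
#' channels); half resolution along rows (stride (2,1), `2c` channels,
#' restored by a transposed convolution with stride (2,1) to `c`); and
#' half resolution along columns (stride (1,2), mirrored). The three
#' routes are concatenated, so output channels are `3c` at the input
#' resolution. Spatial dims must be even.
#'
#' @param in_ch input channels `c`.
#' @param norm batch normalization flag.
#' @export
multires_block <- function(in_ch, norm = TRUE) {
  m <- new_module("multires_block")
  c1 <- in_ch
  m$children <- list(
    full = conv_unit(in_ch, c1, k = c(3, 3), norm = norm),
    down_r = conv_unit(in_ch, 2L * c1, k = c(3, 3), stride = c(2, 1),
                       norm = norm),
    up_r = conv_unit(2L * c1, c1, k = c(3, 3), stride = c(2, 1),
                     transposed = TRUE, norm = norm),
    down_c = conv_unit(in_ch, 2L * c1, k = c(3, 3), stride = c(1, 2),
                       norm = norm),
    up_c = conv_unit(2L * c1, c1, k = c(3, 3), stride = c(1, 2),
                     transposed = TRUE, norm = norm)
  )
  m$out_ch <- 3L * c1
  m$forward <- function(x, training = TRUE) {
    d <- dim(ag_value(x))
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
      stop("multires_block requires even spatial dims, got ", d[1], "x", d[2])
    }
    r1 <- m$children$full$forward(x, training)
    r2 <- m$children$up_r$forward(m$children$down_r$forward(x, training), training)
    r3 <- m$children$up_c$forward(m$children$down_c$forward(x, training), training)
    op_concat(list(r1, r2, r3))
  }
  m
}

#' Multi-scale pooling block
#'
#' Four parallel stride-2 convolutions with kernel sizes 2x2, 3x3, 4x4
#' and 5x5 (per-branch padding `floor((k - 1) / 2)` so all four emit the
#' same spatial size, input/2 for even inputs), each followed by a 1x1
#' convolution to `m/4` channels, then concatenated: output channels
#' equal input channels `m`, spatial dims halve.
#'
#' @param in_ch input channels `m`; must be divisible by 4.
#' @param norm batch normalization flag.
#' @export
multiscale_pool_block <- function(in_ch, norm = TRUE) {
  if (in_ch %% 4L != 0L) stop("multiscale_pool_block: channels (", in_ch,
                              ") must be divisible by 4")
  m <- new_module("multiscale_pool")
  quarter <- in_ch %/% 4L
  mk <- function(k) list(
    scale = conv_unit(in_ch, quarter, k = c(k, k), stride = c(2, 2),
                      pad = rep((k - 1L) %/% 2L, 2), norm = norm),
    proj = conv_unit(quarter, quarter, k = c(1, 1), norm = norm)
  )
  m$children <- list(k2 = mk(2L), k3 = mk(3L), k4 = mk(4L), k5 = mk(5L))
  m$forward <- function(x, training = TRUE) {
    d <- dim(ag_value(x))
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
      stop("multiscale_pool_block requires even spatial dims")
    }
    branches <- lapply(m$children, function(br) {
      br$proj$forward(br$scale$forward(x, training), training)
    })
    op_concat(branches)
  }
  m
}
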