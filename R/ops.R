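## Differentiable tensor operations on (H, W, C, N) arrays.
##
## Each op takes nodes (or plain arrays, treated as constants), computes
## its value through the compiled kernels, and registers a backward
## closure on the tape. Gradients are only computed for parents that
## need them, so e.g. the fixed perceptual extractor propagates
## gradients through its convolutions without ever forming weight
## gradients.

# broadcast a per-channel vector over an (H, W, C, N) array
bc_ch <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

# per-channel sums over (H, W, N), without permuting the array
ch_sum <- function(x) {
  d <- dim(x)
  percn <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(percn, d[3], d[4])
}

#' 2D convolution op
#'
#' @param x input node, (H, W, Cin, N).
#' @param w weight node, (kh, kw, Cin, Cout).
#' @param b bias node of length Cout, or `NULL`.
#' @param stride,pad,dil length-2 integer vectors (row, col).
#' @keywords internal
op_conv <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                    dil = c(1L, 1L)) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else ag_value(b)
  y <- cpp_conv_fwd(xv, wv, bv, stride[1], stride[2], pad[1], pad[2],
                    dil[1], dil[2])
  H <- dim(xv)[1]; W <- dim(xv)[2]; kh <- dim(wv)[1]; kw <- dim(wv)[2]
  ag_op(y, list(x, w, b), function(g) {
    list(
      if (needs_grad(x)) cpp_conv_bwd_data(g, wv, H, W, stride[1], stride[2],
                                           pad[1], pad[2], dil[1], dil[2]),
      if (needs_grad(w)) cpp_conv_bwd_weight(xv, g, kh, kw, stride[1], stride[2],
                                             pad[1], pad[2], dil[1], dil[2]),
      if (!is.null(b) && needs_grad(b)) cpp_conv_bwd_bias(g)
    )
  })
}

#' Transposed 2D convolution op
#'
#' The forward pass is the backward-data pass of an ordinary convolution
#' with the same geometry, so the weight is stored in that convolution's
#' orientation: (kh, kw, Cout, Cin). Output size per axis is
#' `(i - 1) * s - 2p + k + a` with output padding `a`.
#' @keywords internal
op_conv_transpose <- function(x, w, b = NULL, stride = c(2L, 2L),
                              pad = c(1L, 1L), outpad = c(1L, 1L)) {
  xv <- ag_value(x); wv <- ag_value(w)
  d <- dim(xv)
  kh <- dim(wv)[1]; kw <- dim(wv)[2]
  Ho <- (d[1] - 1L) * stride[1] - 2L * pad[1] + kh + outpad[1]
  Wo <- (d[2] - 1L) * stride[2] - 2L * pad[2] + kw + outpad[2]
  y <- cpp_conv_bwd_data(xv, wv, Ho, Wo, stride[1], stride[2],
                         pad[1], pad[2], 1L, 1L)
  if (!is.null(b)) {
    bv <- ag_value(b)
    y <- y + bc_ch(bv, dim(y))
  }
  ag_op(y, list(x, w, b), function(g) {
    list(
      if (needs_grad(x)) cpp_conv_fwd(g, wv, numeric(0), stride[1], stride[2],
                                      pad[1], pad[2], 1L, 1L),
      if (needs_grad(w)) cpp_conv_bwd_weight(g, xv, kh, kw, stride[1], stride[2],
                                             pad[1], pad[2], 1L, 1L),
      if (!is.null(b) && needs_grad(b)) cpp_conv_bwd_bias(g)
    )
  })
}

#' @keywords internal
op_relu <- function(x) {
  xv <- ag_value(x)
  mask <- xv > 0
  ag_op(xv * mask, list(x), function(g) list(g * mask))
}

#' @keywords internal
op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_value(x)))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

#' Channel-wise concatenation of a list of (H, W, C_j, N) nodes
#' @keywords internal
op_concat <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  chs <- vapply(vals, function(v) dim(v)[3], integer(1))
  Ctot <- sum(chs)
  out <- array(0, dim = c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ag_op(out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      ck <- chs[k]
      if (needs_grad(xs[[k]])) {
        res[[k]] <- g[, , at + seq_len(ck), , drop = FALSE]
      }
      at <- at + ck
    }
    res
  })
}

#' @keywords internal
op_avgpool <- function(x, f = c(2L, 2L)) {
  xv <- ag_value(x)
  ag_op(cpp_avgpool_fwd(xv, f[1], f[2]), list(x),
        function(g) list(cpp_avgpool_bwd(g, f[1], f[2])))
}

#' @keywords internal
op_upsample <- function(x, f = c(2L, 2L)) {
  xv <- ag_value(x)
  ag_op(cpp_upsample_fwd(xv, f[1], f[2]), list(x),
        function(g) list(cpp_upsample_bwd(g, f[1], f[2])))
}

#' 2x2 stride-2 max pooling
#' @keywords internal
op_maxpool <- function(x) {
  xv <- ag_value(x)
  r <- cpp_maxpool_fwd(xv)
  H <- dim(xv)[1]; W <- dim(xv)[2]
  ag_op(r$y, list(x), function(g) list(cpp_maxpool_bwd(g, r$idx, H, W)))
}

#' Element-wise product (stage gating); shapes must match, except that a
#' single-channel factor broadcasts over the other's channels.
#' @keywords internal
op_mul <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  if (!identical(dim(xv), dim(yv))) {
    stop("op_mul: dimension mismatch")
  }
  ag_op(xv * yv, list(x, y), function(g) {
    list(if (needs_grad(x)) g * yv, if (needs_grad(y)) g * xv)
  })
}

#' Batch normalization over (H, W, N) per channel
#'
#' @param layer environment caching running statistics.
#' @keywords internal
op_batchnorm <- function(x, gamma, beta, layer, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  xv <- ag_value(x)
  d <- dim(xv)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- ch_sum(xv) / m
    xc <- xv - bc_ch(mu, d)
    va <- ch_sum(xc * xc) / m
    layer$run_mean <- (1 - momentum) * layer$run_mean + momentum * mu
    layer$run_var <- (1 - momentum) * layer$run_var + momentum * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
    xc <- xv - bc_ch(mu, d)
  }
  istd <- 1 / sqrt(va + eps)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  # y = xc * (istd * gamma) + beta, fused into two broadcasts
  y <- xc * bc_ch(istd * gv, d) + bc_ch(bv, d)
  ag_op(y, list(x, gamma, beta), function(g) {
    xhat <- xc * bc_ch(istd, d)
    dgamma <- if (needs_grad(gamma)) ch_sum(g * xhat)
    dbeta <- if (needs_grad(beta)) ch_sum(g)
    dx <- NULL
    if (needs_grad(x)) {
      if (training) {
        s1 <- ch_sum(g)
        s2 <- ch_sum(g * xhat)
        # dx = gamma*istd/m * (m*g - s1 - xhat*s2), channel-wise
        dx <- bc_ch(gv * istd, d) *
          (g - bc_ch(s1 / m, d) - xhat * bc_ch(s2 / m, d))
      } else {
        dx <- g * bc_ch(gv * istd, d)
      }
    }
    list(dx, dgamma, dbeta)
  })
}

#' Straight-through hard gate: thresholds on the forward pass, passes
#' the gradient through unchanged (identity estimator), so a hard gate
#' stays usable inside end-to-end training.
#' @keywords internal
op_hard_gate_st <- function(prob, threshold) {
  pv <- ag_value(prob)
  ag_op((pv >= threshold) * 1, list(prob), function(g) list(g))
}

#' Weighted sum of scalar nodes
#' @keywords internal
op_scalar_wsum <- function(xs, weights) {
  v <- sum(vapply(xs, function(x) as.numeric(ag_value(x)), numeric(1)) * weights)
  ag_op(v, xs, function(g) {
    lapply(seq_along(xs), function(k) if (needs_grad(xs[[k]])) g * weights[k])
  })
}
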