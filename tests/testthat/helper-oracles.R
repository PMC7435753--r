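# Independent oracles used across the suite; deliberately brute-force
# and independent of the package's compiled kernels.

# count pixels whose center lies within d/2 of (cr, cc) on an L x L grid
brute_disc_count <- function(L, cr, cc, d) {
  g <- expand.grid(r = seq_len(L), c = seq_len(L))
  sum((g$r - cr)^2 + (g$c - cc)^2 <= (d / 2)^2)
}

# naive dense 2D convolution with per-axis stride/pad/dilation
brute_conv <- function(x, w, sh = 1, sw = 1, ph = 0, pw = 0, dh = 1, dw = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  nh <- kh + (kh - 1) * (dh - 1); nw <- kw + (kw - 1) * (dw - 1)
  Ho <- (H + 2 * ph - nh) %/% sh + 1; Wo <- (W + 2 * pw - nw) %/% sw + 1
  y <- array(0, c(Ho, Wo, Co, dim(x)[4]))
  for (n in seq_len(dim(x)[4])) for (co in seq_len(Co)) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      s <- 0
      for (c in seq_len(C)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        hi <- (ho - 1) * sh - ph + (ki - 1) * dh + 1
        wi <- (wo - 1) * sw - pw + (kj - 1) * dw + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          s <- s + x[hi, wi, c, n] * w[ki, kj, c, co]
        }
      }
      y[ho, wo, co, n] <- s
    }
  }
  y
}

# expand a kernel by inserting d-1 zeros between taps
inflate_kernel <- function(w, d) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  nh <- kh + (kh - 1) * (d - 1); nw <- kw + (kw - 1) * (d - 1)
  wi <- array(0, c(nh, nw, dim(w)[3], dim(w)[4]))
  wi[seq(1, nh, by = d), seq(1, nw, by = d), , ] <- w
  wi
}

# 8-connected labelling by breadth-first flood fill
brute_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cl <- p[2] + dc
        if (r >= 1 && r <= H && cl >= 1 && cl <= W &&
            mask[r, cl] != 0 && lab[r, cl] == 0L) {
          lab[r, cl] <- nxt
          queue[[length(queue) + 1L]] <- c(r, cl)
        }
      }
    }
  }
  lab
}

# numeric gradient of a scalar function of an array or vector
brute_num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
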