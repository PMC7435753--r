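## Layer and module plumbing: parameter initialization, the standard
## convolution unit (conv / transposed conv + batch norm + activation),
## recursive parameter collection and the Adam optimizer.
##
## A "module" is an environment with a `forward(x, training)` function,
## a `params` list of trainable nodes and a `children` list of
## sub-modules. Weights are He-initialized from R's RNG so a fixed seed
## reproduces a network bit-exactly.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("nc_", type), "nc_module")
  m
}

# He-normal initialization; fan_in = kh * kw * Cin
init_weight <- function(d, fan_in) {
  ag_node(array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d),
          requires_grad = TRUE)
}

init_const <- function(n, value) {
  ag_node(rep(value, n), requires_grad = TRUE)
}

#' Standard convolution unit
#'
#' One (possibly dilated or transposed) convolution followed by optional
#' batch normalization and an activation. `pad = "same"` resolves to
#' `floor(((k - 1) * d) / 2)` per axis, which preserves spatial size at
#' stride 1 for odd kernels.
#'
#' @param in_ch,out_ch channel counts.
#' @param k kernel size, length-2 (row, col).
#' @param stride,dil length-2 integer vectors.
#' @param pad `"same"` or explicit length-2 zero-padding.
#' @param transposed transposed (fractional-stride) convolution; output
#'   size is `i * s` per axis.
#' @param activation `"relu"`, `"sigmoid"` or `"none"`.
#' @param norm apply batch normalization before the activation.
#' @keywords internal
conv_unit <- function(in_ch, out_ch, k = c(3L, 3L), stride = c(1L, 1L),
                      dil = c(1L, 1L), pad = "same", transposed = FALSE,
                      activation = "relu", norm = TRUE, bias_init = 0) {
  m <- new_module("conv_unit")
  k <- as.integer(rep(k, length.out = 2))
  stride <- as.integer(rep(stride, length.out = 2))
  dil <- as.integer(rep(dil, length.out = 2))
  if (identical(pad, "same")) {
    pad <- ((k - 1L) * dil) %/% 2L
  }
  pad <- as.integer(rep(pad, length.out = 2))
  m$k <- k; m$stride <- stride; m$dil <- dil; m$pad <- pad
  m$transposed <- transposed
  m$activation <- activation
  m$norm <- norm
  if (transposed) {
    # weight in the underlying convolution's orientation (out, in)
    m$params$w <- init_weight(c(k, out_ch, in_ch), k[1] * k[2] * in_ch)
    m$outpad <- stride + 2L * pad - k
    stopifnot(all(m$outpad >= 0))
  } else {
    m$params$w <- init_weight(c(k, in_ch, out_ch), k[1] * k[2] * in_ch)
  }
  m$params$b <- init_const(out_ch, bias_init)
  if (norm) {
    m$params$gamma <- init_const(out_ch, 1)
    m$params$beta <- init_const(out_ch, 0)
    m$run_mean <- rep(0, out_ch)
    m$run_var <- rep(1, out_ch)
  }
  m$forward <- function(x, training = TRUE) {
    y <- if (transposed) {
      op_conv_transpose(x, m$params$w, m$params$b, stride = m$stride,
                        pad = m$pad, outpad = m$outpad)
    } else {
      op_conv(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad,
              dil = m$dil)
    }
    if (m$norm) {
      y <- op_batchnorm(y, m$params$gamma, m$params$beta, m, training = training)
    }
    switch(m$activation,
           relu = op_relu(y),
           sigmoid = op_sigmoid(y),
           none = y,
           stop("unknown activation: ", m$activation))
  }
  m
}

#' Collect all trainable parameter nodes of a module tree
#' @param module a module (or list of modules).
#' @return flat list of parameter nodes.
#' @keywords internal
collect_params <- function(module) {
  out <- list()
  walk <- function(m) {
    if (is.list(m) && !is.environment(m)) {
      for (el in m) walk(el)
    } else if (inherits(m, "nc_module")) {
      for (p in m$params) if (isTRUE(p$requires_grad)) out[[length(out) + 1L]] <<- p
      for (ch in m$children) walk(ch)
    }
  }
  walk(module)
  out
}

#' Count trainable scalars of a module tree
#' @keywords internal
count_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

#' Extract / restore all parameter values (and batch-norm running
#' statistics) of a module tree, for checkpointing.
#' @keywords internal
module_state <- function(module) {
  state <- list()
  walk <- function(m, path) {
    if (is.list(m) && !is.environment(m)) {
      for (k in seq_along(m)) walk(m[[k]], paste0(path, "[", k, "]"))
    } else if (inherits(m, "nc_module")) {
      for (nm in names(m$params)) {
        state[[paste0(path, "$", nm)]] <<- m$params[[nm]]$value
      }
      if (isTRUE(m$norm)) {
        state[[paste0(path, "$run_mean")]] <<- m$run_mean
        state[[paste0(path, "$run_var")]] <<- m$run_var
      }
      for (k in seq_along(m$children)) walk(m$children[[k]], paste0(path, "/", k))
    }
  }
  walk(module, "")
  state
}

#' @keywords internal
module_load_state <- function(module, state) {
  i <- 0L
  walk <- function(m, path) {
    if (is.list(m) && !is.environment(m)) {
      for (k in seq_along(m)) walk(m[[k]], paste0(path, "[", k, "]"))
    } else if (inherits(m, "nc_module")) {
      for (nm in names(m$params)) {
        key <- paste0(path, "$", nm)
        stopifnot(key %in% names(state))
        m$params[[nm]]$value <- state[[key]]
      }
      if (isTRUE(m$norm)) {
        m$run_mean <- state[[paste0(path, "$run_mean")]]
        m$run_var <- state[[paste0(path, "$run_var")]]
      }
      for (k in seq_along(m$children)) walk(m$children[[k]], paste0(path, "/", k))
    }
  }
  walk(module, "")
  invisible(module)
}

#' Adam optimizer state for a list of parameter nodes
#' @keywords internal
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0),
    t = 0L
  )
}

#' One Adam step with decoupled L2 regularization added to the gradient
#' @keywords internal
adam_step <- function(state, params, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
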