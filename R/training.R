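## End-to-end optimization of the cascade as one network: a single Adam
## optimizer over the union of all three sub-networks' parameters, the
## joint loss computed on the final nodule map each step, soft gating at
## stage boundaries so gradients cross them.

#' Reference training hyperparameters
#'
#' Learning rate 0.001, batch size 40, 100 epochs, loss weights
#' (0.9, 0.9, 0.999) and weight decay 1e-4. Desk-scale runs typically
#' override `batch_size` and `epochs`.
#'
#' @param learning_rate positive step size.
#' @param weight_decay L2 regularization coefficient.
#' @param batch_size samples per optimization step (>= 1).
#' @param epochs passes over the training set (>= 1).
#' @param loss_weights a [loss_weights()].
#' @param seed RNG seed governing initialization, the data split and
#'   batch order.
#' @return object of class `"hyperparameters"`.
#' @export
default_hyperparameters <- function(learning_rate = 0.001,
                                    weight_decay = 1e-4,
                                    batch_size = 40L,
                                    epochs = 100L,
                                    loss_weights = nodulecascade::loss_weights(),
                                    seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_weights = loss_weights,
                 seed = as.integer(seed)),
            class = "hyperparameters")
}

stack_batch <- function(samples, field) {
  mats <- lapply(samples, function(s) {
    if (field == "image") s$image$values else s[[field]]
  })
  d <- dim(mats[[1]])
  arr <- array(0, dim = c(d[1], d[2], 1L, length(mats)))
  for (i in seq_along(mats)) arr[, , 1L, i] <- mats[[i]]
  arr
}

#' Train the cascade end-to-end
#'
#' One optimizer updates every parameter of all three sub-networks; the
#' joint loss is computed on the final nodule map against the nodule
#' ground truth each step (optionally plus per-stage auxiliary dice
#' terms against the parenchyma and candidate ground truths). Gating is
#' soft during training so the loss is differentiable through stage
#' boundaries. Deterministic for a fixed configuration and seed.
#'
#' @param cascade a `nodule_cascade`; its weights are re-initialized
#'   from the seed unless `reinitialize = FALSE`.
#' @param samples list of phantom samples sharing spatial dims
#'   (divisible by 8).
#' @param hyper a [default_hyperparameters()].
#' @param extractor a [perceptual_extractor()] for the perceptual term;
#'   built at full width from the seed when `NULL` and `mu2 > 0`.
#' @param val_fraction held-out fraction for per-epoch validation
#'   metrics (0 disables).
#' @param aux_loss_weight weight of the per-stage auxiliary dice losses
#'   (0 = off, the default: supervision on the final map only).
#' @param checkpoint_dir directory for per-epoch checkpoints (`NULL` =
#'   none).
#' @param grad_clip global gradient-norm ceiling (`Inf` disables);
#'   gradients are rescaled when their joint norm exceeds it.
#' @param hard_gate_from fraction of the epochs after which training
#'   switches from soft gates to straight-through hard gates (hard
#'   forward pass at the configured threshold, identity gradient), so
#'   the stages calibrate to the hard gating used at inference; 1
#'   disables the switch (soft gating throughout).
#' @param reinitialize draw fresh seeded weights before training.
#' @param verbose print a line per epoch.
#' @return object of class `"training_history"`: per-iteration losses
#'   (raw and normalized to `[0, 1]` for reporting), per-epoch
#'   validation dice, and the epoch count.
#' @export
train_cascade <- function(cascade, samples, hyper = default_hyperparameters(),
                          extractor = NULL, val_fraction = 0.2,
                          aux_loss_weight = 0, checkpoint_dir = NULL,
                          grad_clip = 100, hard_gate_from = 0.5,
                          reinitialize = TRUE, verbose = FALSE) {
  stopifnot(inherits(cascade, "nodule_cascade"), length(samples) >= 1)
  dims <- dim(samples[[1]]$image$values)
  if (any(dims %% 8L != 0L)) stop("sample dims must be divisible by 8")
  lw <- hyper$loss_weights

  set.seed(hyper$seed)
  if (reinitialize) {
    fresh <- build_cascade(cascade$config)
    module_load_state(unclass(cascade)[1:3], module_state(unclass(fresh)[1:3]))
  }
  if (is.null(extractor) && lw$mu2 > 0) {
    extractor <- perceptual_extractor(seed = hyper$seed)
  }

  n <- length(samples)
  n_val <- floor(n * val_fraction)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!length(train_idx)) stop("empty training split")

  params <- collect_params(unclass(cascade)[1:3])
  opt <- adam_init(params)

  iter_rows <- list()
  val_dice <- rep(NA_real_, hyper$epochs)
  it <- 0L

  for (epoch in seq_len(hyper$epochs)) {
    gate <- if (epoch > ceiling(hyper$epochs * hard_gate_from)) "st" else "soft"
    order_idx <- train_idx[sample.int(length(train_idx))]
    batches <- split(order_idx, ceiling(seq_along(order_idx) / hyper$batch_size))
    for (bt in batches) {
      bs <- samples[bt]
      x <- ag_node(stack_batch(bs, "image"))
      gt <- stack_batch(bs, "nodule_mask")
      ag_clear_tape()
      loss <- ag_record({
        out <- cascade_forward_nodes(cascade, x, training = TRUE, gate = gate)
        lj <- op_joint_loss(out$nodule, gt, lw, extractor)
        if (aux_loss_weight > 0) {
          # dense per-stage supervision: dice + pixel-wise MSE against the
          # parenchyma and candidate ground truths
          g1 <- stack_batch(bs, "parenchyma_mask")
          g2 <- stack_batch(bs, "candidate_mask")
          total <- op_scalar_wsum(
            list(lj,
                 op_dice_loss(out$parenchyma, g1),
                 op_pixel_loss(out$parenchyma, g1),
                 op_dice_loss(out$candidate, g2),
                 op_pixel_loss(out$candidate, g2)),
            c(1, rep(aux_loss_weight, 4)))
          attr(total, "components") <- attr(lj, "components")
          total
        } else {
          lj
        }
      })
      lv <- as.numeric(ag_value(loss))
      if (!is.finite(lv)) {
        stop("non-finite loss at epoch ", epoch, ", iteration ", it + 1L,
             " (components: ",
             paste(signif(attr(loss, "components"), 4), collapse = ", "), ")")
      }
      ag_backward(loss)
      if (is.finite(grad_clip)) {
        gn <- sqrt(sum(vapply(params, function(p) {
          if (is.null(p$grad)) 0 else sum(p$grad^2)
        }, numeric(1))))
        if (gn > grad_clip) {
          for (p in params) {
            if (!is.null(p$grad)) p$grad <- p$grad * (grad_clip / gn)
          }
        }
      }
      opt <- adam_step(opt, params, hyper$learning_rate, hyper$weight_decay)
      ag_zero_grad(params)
      it <- it + 1L
      comp <- attr(loss, "components")
      iter_rows[[it]] <- c(
        epoch = epoch, iteration = it, loss = lv,
        pixel = comp[["pix"]],
        perceptual = if ("perc" %in% names(comp)) comp[["perc"]] else NA_real_,
        dice = comp[["dice"]])
    }
    if (length(val_idx)) {
      val_dice[epoch] <- mean(vapply(samples[val_idx], function(s) {
        pb <- drop_ch(cascade_forward(cascade, s$image$values)$nodule_prob) >= 0.5
        d <- dice_coefficient(pb * 1L, s$nodule_mask)
        if (is.na(d)) as.numeric(sum(pb) == 0) else d
      }, numeric(1)))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_cascade(cascade, file.path(checkpoint_dir,
                                      sprintf("epoch_%03d.rds", epoch)))
    }
    if (verbose) {
      ep_loss <- vapply(iter_rows, function(r) r[["loss"]], numeric(1))
      ep_of <- vapply(iter_rows, function(r) r[["epoch"]], numeric(1))
      message(sprintf("epoch %3d/%d  loss %.4f  val dice %s",
                      epoch, hyper$epochs, mean(ep_loss[ep_of == epoch]),
                      ifelse(is.na(val_dice[epoch]), "-",
                             sprintf("%.3f", val_dice[epoch]))))
    }
  }

  iters <- as.data.frame(do.call(rbind, iter_rows))
  rng <- range(iters$loss)
  iters$loss_norm <- if (diff(rng) > 0) (iters$loss - rng[1]) / diff(rng)
                     else rep(0, nrow(iters))
  structure(list(iterations = iters, val_dice = val_dice,
                 epochs = hyper$epochs, hyper = hyper),
            class = "training_history")
}

#' @export
print.training_history <- function(x, ...) {
  n <- nrow(x$iterations)
  cat(sprintf("<training_history> %d iterations over %d epoch(s)\n",
              n, x$epochs))
  cat(sprintf("  loss: first %.4f -> last %.4f\n",
              x$iterations$loss[1], x$iterations$loss[n]))
  if (any(!is.na(x$val_dice))) {
    cat(sprintf("  final val dice: %.4f\n", x$val_dice[x$epochs]))
  }
  invisible(x)
}
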