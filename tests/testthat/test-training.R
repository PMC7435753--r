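# Training: hyperparameter defaults, zero-step identity, descent,
# branch coverage, reproducibility.

nc <- asNamespace("nodulecascade")

test_that("reference hyperparameters carry the training setup", {
  h <- default_hyperparameters()
  expect_equal(h$learning_rate, 0.001)
  expect_equal(h$batch_size, 40L)
  expect_equal(h$epochs, 100L)
  expect_equal(unlist(h$loss_weights[c("mu1", "mu2", "mu3")]),
               c(mu1 = 0.9, mu2 = 0.9, mu3 = 0.999))
  expect_equal(h$weight_decay, 1e-4)
  expect_error(default_hyperparameters(batch_size = 0), "batch_size")
  expect_error(default_hyperparameters(epochs = 0), "epochs")
})

test_that("zero learning rate leaves the weights untouched", {
  ds <- generate_dataset(2, tiny_params(), seed = 1, negative_fraction = 0)
  set.seed(2); cas <- build_cascade(tiny_config())
  before <- nc$module_state(unclass(cas)[1:3])
  hy <- default_hyperparameters(learning_rate = 0, batch_size = 2, epochs = 1,
                                loss_weights = loss_weights(0.9, 0, 0.999),
                                seed = 3)
  train_cascade(cas, ds, hy, val_fraction = 0, reinitialize = FALSE)
  after <- nc$module_state(unclass(cas)[1:3])
  # parameters identical (batch-norm running stats are state, not weights)
  for (nm in names(before)) {
    if (!grepl("run_(mean|var)", nm)) expect_identical(after[[nm]], before[[nm]])
  }
})

test_that("a short seeded run descends on average", {
  ds <- generate_dataset(8, tiny_params(), seed = 4)
  set.seed(5); cas <- build_cascade(tiny_config())
  hy <- default_hyperparameters(batch_size = 4, epochs = 5, seed = 5,
                                loss_weights = loss_weights(0.9, 0, 0.999))
  h <- train_cascade(cas, ds, hy, val_fraction = 0, aux_loss_weight = 1)
  first <- mean(h$iterations$loss[h$iterations$epoch == 1])
  last <- mean(h$iterations$loss[h$iterations$epoch == 5])
  expect_lt(last, first)
  # normalized trajectory spans [0, 1] without reordering the raw one
  expect_equal(range(h$iterations$loss_norm), c(0, 1))
  expect_equal(order(h$iterations$loss), order(h$iterations$loss_norm))
})

test_that("an all-negative dataset trains through the empty-GT dice branch", {
  ds <- generate_dataset(4, tiny_params(), seed = 6, negative_fraction = 1)
  expect_true(all(vapply(ds, function(s) sum(s$nodule_mask) == 0, logical(1))))
  set.seed(7); cas <- build_cascade(tiny_config())
  hy <- default_hyperparameters(batch_size = 4, epochs = 1, seed = 7,
                                loss_weights = loss_weights(0.9, 0, 0.999))
  expect_no_error(train_cascade(cas, ds, hy, val_fraction = 0))
})

test_that("every parameter of all three sub-networks receives a gradient", {
  ds <- generate_dataset(2, tiny_params(), seed = 8, negative_fraction = 0)
  set.seed(9); cas <- build_cascade(tiny_config())
  ex <- tiny_extractor()
  x <- nc$ag_node(nc$stack_batch(ds, "image"))
  gt <- nc$stack_batch(ds, "nodule_mask")
  nc$ag_clear_tape()
  loss <- nc$ag_record({
    out <- nc$cascade_forward_nodes(cas, x, training = TRUE, gate = "soft")
    nc$op_joint_loss(out$nodule, gt, loss_weights(), ex)
  })
  nc$ag_backward(loss)
  params <- nc$collect_params(unclass(cas)[1:3])
  expect_gt(length(params), 50)
  for (p in params) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
  }
  nc$ag_zero_grad(params)
})

test_that("training is reproducible from the seed", {
  ds <- generate_dataset(4, tiny_params(), seed = 10)
  hy <- default_hyperparameters(batch_size = 2, epochs = 2, seed = 11,
                                loss_weights = loss_weights(0.9, 0, 0.999))
  run <- function() {
    set.seed(99); cas <- build_cascade(tiny_config())
    train_cascade(cas, ds, hy, val_fraction = 0.25,
                  aux_loss_weight = 1)$iterations
  }
  expect_identical(run()$loss, run()$loss)
})

test_that("checkpoints are written per epoch when requested", {
  ds <- generate_dataset(2, tiny_params(), seed = 12, negative_fraction = 0)
  set.seed(13); cas <- build_cascade(tiny_config())
  dir <- tempfile(); hy <- default_hyperparameters(
    batch_size = 2, epochs = 2, seed = 13,
    loss_weights = loss_weights(0.9, 0, 0.999))
  train_cascade(cas, ds, hy, val_fraction = 0, checkpoint_dir = dir)
  expect_setequal(list.files(dir), c("epoch_001.rds", "epoch_002.rds"))
  unlink(dir, recursive = TRUE)
})
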