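# Reverse-mode tape correctness against numeric differentiation.

nc <- asNamespace("nodulecascade")

test_that("conv unit gradients match numeric differentiation", {
  set.seed(11)
  u <- nc$conv_unit(2L, 3L, stride = c(2, 1), dil = c(2, 1))
  x <- nc$ag_node(rand_feature(8, 8, 2, N = 2, seed = 12), requires_grad = TRUE)
  lossfun <- function() {
    u$run_mean <- rep(0, 3); u$run_var <- rep(1, 3)
    y <- u$forward(x, training = TRUE)
    v <- nc$ag_value(y)
    nc$ag_op(sum(v^2), list(y), function(g) list(g * 2 * v))
  }
  L <- nc$ag_record(lossfun())
  nc$ag_backward(L)
  params <- nc$collect_params(u)
  for (p in c(list(x), params)) {
    expect_false(is.null(p$grad))
    f <- function(v) {
      old <- p$value; p$value <- v
      on.exit(p$value <- old)
      as.numeric(nc$ag_value(nc$ag_no_grad(lossfun())))
    }
    expect_lt(max(abs(p$grad - brute_num_grad(f, p$value))), 1e-4)
  }
})

test_that("transposed conv unit gradients match numeric differentiation", {
  set.seed(13)
  u <- nc$conv_unit(3L, 2L, stride = c(2, 2), transposed = TRUE, norm = FALSE,
                    activation = "none")
  x <- nc$ag_node(rand_feature(4, 4, 3, seed = 14), requires_grad = TRUE)
  lossfun <- function() {
    y <- u$forward(x, training = TRUE)
    v <- nc$ag_value(y)
    nc$ag_op(sum(v^3), list(y), function(g) list(g * 3 * v^2))
  }
  L <- nc$ag_record(lossfun())
  y <- nc$ag_no_grad(u$forward(x, training = TRUE))
  expect_equal(dim(nc$ag_value(y)), c(8, 8, 2, 1))
  nc$ag_backward(L)
  for (p in c(list(x), nc$collect_params(u))) {
    f <- function(v) {
      old <- p$value; p$value <- v
      on.exit(p$value <- old)
      as.numeric(nc$ag_value(nc$ag_no_grad(lossfun())))
    }
    expect_lt(max(abs(p$grad - brute_num_grad(f, p$value))), 1e-4)
  }
})

test_that("loss op gradients match numeric differentiation", {
  set.seed(15)
  gt <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  gt0 <- array(0, c(8, 8, 1, 1))
  ex <- tiny_extractor()
  for (gtv in list(gt, gt0)) {
    x <- nc$ag_node(array(runif(64), c(8, 8, 1, 1)), requires_grad = TRUE)
    lossfun <- function() {
      nc$op_joint_loss(x, gtv, loss_weights(), ex)
    }
    L <- nc$ag_record(lossfun())
    nc$ag_backward(L)
    f <- function(v) {
      old <- x$value; x$value <- v
      on.exit(x$value <- old)
      as.numeric(nc$ag_value(nc$ag_no_grad(lossfun())))
    }
    expect_lt(max(abs(x$grad - brute_num_grad(f, x$value))), 1e-4)
  }
})

test_that("tape is cleared after backward and no-grad mode records nothing", {
  x <- nc$ag_node(array(1, c(4, 4, 1, 1)), requires_grad = TRUE)
  y <- nc$ag_no_grad(nc$op_relu(x))
  expect_identical(nc$.ag$len, 0L)
  L <- nc$ag_record({
    z <- nc$op_relu(x)
    v <- nc$ag_value(z)
    nc$ag_op(sum(v), list(z), function(g) list(array(g, dim(v))))
  })
  expect_gt(nc$.ag$len, 0L)
  nc$ag_backward(L)
  expect_identical(nc$.ag$len, 0L)
  expect_equal(x$grad, array(1, c(4, 4, 1, 1)))
  nc$ag_zero_grad(list(x))
  expect_null(x$grad)
})
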