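# Loss algebra: exact fixtures, the negative-sample branch, symmetry,
# and agreement with brute-force recomputation.

test_that("pixel loss is the normalized squared error", {
  a <- matrix(c(0.2, 0.8, 0.5, 0.1), 2)
  expect_identical(pixel_loss(a, a), 0)
  expect_equal(pixel_loss(matrix(1, 2, 2), matrix(0, 2, 2)), 1.0)
  b <- a; b[2, 1] <- b[2, 1] + 1
  expect_equal(pixel_loss(b, a), 0.25)
  expect_error(pixel_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("dice loss matches set counts on binary masks", {
  m <- function(v) matrix(v, 4, 4)
  gt <- m(0); gt[1:2, 1:2] <- 1
  expect_equal(dice_loss(gt, gt), 0)
  disj <- m(0); disj[3:4, 3:4] <- 1
  expect_equal(dice_loss(disj, gt), 1)
  half <- m(0); half[1:2, 2:3] <- 1 # overlap on 2 of 4+4
  expect_equal(dice_loss(half, gt), 0.5)
  # brute-force set-count dice on random binary masks
  set.seed(8)
  for (i in 1:5) {
    p <- matrix(rbinom(36, 1, 0.4), 6)
    g <- matrix(rbinom(36, 1, 0.4), 6)
    if (sum(g) == 0) next
    want <- 1 - 2 * sum(p & g) / (sum(p) + sum(g))
    expect_equal(dice_loss(p, g), want)
  }
  expect_error(dice_loss(m(0.5), m(0.5)), "binary")
})

test_that("empty ground truth triggers the normalized L1 branch", {
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(matrix(0.5, 4, 4), z), 0.5)
  # continuity: as pred -> 0 the negative branch -> 0
  vals <- vapply(c(0.2, 0.05, 0.01, 0.001), function(eps) {
    dice_loss(matrix(eps, 4, 4), z)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-2)
  expect_equal(dice_loss(z, z), 0)
})

test_that("perceptual loss is zero at identity, symmetric, and matches
           a feature-space recomputation", {
  ex <- tiny_extractor()
  set.seed(3)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  expect_identical(perceptual_loss(a, a, ex), 0)
  expect_equal(perceptual_loss(a, b, ex), perceptual_loss(b, a, ex))
  fa <- perceptual_features(ex, a)
  fb <- perceptual_features(ex, b)
  want <- sum((fa - fb)^2) / (dim(fa)[1] * dim(fa)[2])
  expect_equal(perceptual_loss(a, b, ex), want)
  # identical inputs always give identical features (fixed weights)
  expect_identical(fa, perceptual_features(ex, a))
})

test_that("joint loss is the exact weighted sum of its components", {
  ex <- tiny_extractor()
  set.seed(4)
  pred <- matrix(runif(64 * 64), 64)
  gt <- matrix(0, 64, 64); gt[10:14, 20:24] <- 1
  w <- loss_weights(0.9, 0.9, 0.999)
  jl <- joint_loss(pred, gt, w, ex)
  comp <- attr(jl, "components")
  expect_equal(as.numeric(jl),
               0.9 * comp[["pix"]] + 0.9 * comp[["perc"]] + 0.999 * comp[["dice"]])
  expect_equal(comp[["pix"]], pixel_loss(pred, gt))
  expect_equal(comp[["dice"]], dice_loss(pred, gt))
  expect_equal(comp[["perc"]], perceptual_loss(pred, gt, ex))
  # projection onto one component
  expect_equal(as.numeric(joint_loss(pred, gt, loss_weights(1, 0, 0))),
               pixel_loss(pred, gt))
  # perfect prediction vanishes for any weights
  expect_equal(as.numeric(joint_loss(gt, gt, w, ex)), 0)
})

test_that("joint loss is linear in each coefficient", {
  ex <- tiny_extractor()
  set.seed(6)
  pred <- matrix(runif(64 * 64), 64)
  gt <- matrix(0, 64, 64); gt[30:35, 30:35] <- 1
  base <- joint_loss(pred, gt, loss_weights(0.5, 0.5, 0.5), ex)
  for (k in 1:3) {
    w1 <- c(0.5, 0.5, 0.5); w1[k] <- 1.5
    up <- joint_loss(pred, gt, do.call(loss_weights, as.list(w1)), ex)
    comp <- attr(base, "components")
    expect_equal(as.numeric(up) - as.numeric(base), comp[[k]],
                 tolerance = 1e-12)
  }
})

test_that("extractor honours layer counting and tap index", {
  ex3 <- perceptual_extractor(layer_index = 3, width_scale = 1 / 16, seed = 1)
  f3 <- perceptual_features(ex3, matrix(0.5, 32, 32))
  # tap 3 sits after one pool: /2 resolution
  expect_equal(dim(f3)[1:2], c(16, 16))
  exall <- perceptual_extractor(layer_index = 3, width_scale = 1 / 16,
                                seed = 1, counting = "all")
  fall <- perceptual_features(exall, matrix(0.5, 32, 32))
  # counting pools, layer 3 is the pool itself: still /2 but after 2 convs
  expect_equal(dim(fall)[1:2], c(16, 16))
  expect_error(perceptual_extractor(layer_index = 40), "exceeds")
})
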