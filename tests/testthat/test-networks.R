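# Sub-network contracts, gating semantics and the cascade.

nc <- asNamespace("nodulecascade")

test_that("all three sub-networks close over resolution", {
  cfg <- tiny_config()
  set.seed(1)
  nets <- list(build_parenchyma_net(cfg), build_candidate_net(cfg),
               build_determination_net(cfg, in_ch = 2L))
  for (k in seq_along(nets)) {
    in_ch <- if (k == 3) 2L else 1L
    x <- rand_feature(64, 64, in_ch, seed = k)
    y <- block_forward(nets[[k]], x)
    expect_equal(dim(y), c(64, 64, 1, 1))
    expect_true(all(y >= 0 & y <= 1))
    expect_error(block_forward(nets[[k]], rand_feature(60, 64, in_ch)),
                 "divisible by 8")
  }
})

test_that("encoder bookkeeping matches three stride-2 halvings", {
  # 64 -> 8 after three halvings; declared widths reach the deepest stage
  cfg <- cascade_config(width_scale = 1)
  expect_identical(cfg$par_enc[3], 512L)
  expect_equal(64 / 2^3, 8)
})

test_that("stage gate semantics: identity, annihilation, thresholding", {
  set.seed(2)
  img <- matrix(runif(64 * 64), 64)
  ones <- matrix(1, 64, 64)
  zeros <- matrix(0, 64, 64)
  expect_equal(apply_stage_gate(img, ones, "multiply"), img)
  expect_equal(apply_stage_gate(img, zeros, "multiply"), zeros)
  # prob 0.4 region zeroed by a hard 0.5 gate
  prob <- matrix(0.4, 64, 64); prob[1:8, ] <- 0.9
  hard <- apply_stage_gate(img, prob, "multiply", soft = FALSE, threshold = 0.5)
  expect_true(all(hard[9:64, ] == 0))
  expect_equal(hard[1:8, ], img[1:8, ])
  # soft gate keeps the product
  soft <- apply_stage_gate(img, prob, "multiply", soft = TRUE)
  expect_equal(soft, img * prob)
  # concat mode stacks gated image and probability map
  two <- apply_stage_gate(img, prob, "concat", soft = TRUE)
  expect_equal(dim(two), c(64, 64, 2))
  expect_equal(two[, , 1], img * prob)
  expect_equal(two[, , 2], prob)
  expect_error(apply_stage_gate(img, matrix(1, 32, 32)), "mismatch")
})

test_that("gate monotonicity: a smaller gate never increases the gated input", {
  set.seed(3)
  img <- matrix(runif(256), 16)
  g1 <- matrix(runif(256), 16)
  g2 <- pmin(g1, matrix(runif(256), 16)) # pixel-wise <= g1
  a <- apply_stage_gate(img, g1, "multiply", soft = TRUE)
  b <- apply_stage_gate(img, g2, "multiply", soft = TRUE)
  expect_true(all(b <= a + 1e-12))
})

test_that("cascade emits three input-sized maps in [0, 1]", {
  set.seed(4)
  cas <- build_cascade(tiny_config())
  img <- generate_phantom(tiny_params(), seed = 5)$image$values
  out <- cascade_forward(cas, img)
  for (m in out) {
    expect_equal(dim(m)[1:2], c(64, 64))
    expect_true(all(m >= 0 & m <= 1))
  }
  # batched input keeps the batch axis
  batch <- array(img, c(64, 64, 1, 2))
  outb <- cascade_forward(cas, batch)
  expect_equal(dim(outb$nodule_prob), c(64, 64, 1, 2))
})

test_that("an all-ones stage-1 gate propagates the raw image to stage 2", {
  img <- matrix(runif(64 * 64), 64)
  gated <- apply_stage_gate(img, matrix(1, 64, 64), "multiply", soft = FALSE)
  expect_identical(gated, img)
  # and an all-zero parenchyma gate makes the stage-2 input identically 0
  gated0 <- apply_stage_gate(img, matrix(0, 64, 64), "multiply", soft = FALSE)
  expect_true(all(gated0 == 0))
})

test_that("multiply-gating cascade consumes 1-channel stage-3 input", {
  set.seed(6)
  cas <- build_cascade(tiny_config(gating = "multiply"))
  out <- cascade_forward(cas, matrix(runif(64 * 64), 64))
  expect_equal(dim(out$nodule_prob)[1:2], c(64, 64))
})

test_that("checkpoints round-trip the full cascade state", {
  set.seed(7)
  cas <- build_cascade(tiny_config())
  img <- matrix(runif(64 * 64), 64)
  before <- cascade_forward(cas, img)
  f <- tempfile(fileext = ".rds")
  save_cascade(cas, f)
  restored <- load_cascade(f)
  after <- cascade_forward(restored, img)
  expect_identical(before, after)
  unlink(f)
})
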