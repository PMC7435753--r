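# Block contracts and the dilated-convolution size algebra.

test_that("effective kernel size follows n = k + (k-1)(d-1)", {
  expect_identical(effective_kernel_size(3, 1), 3L)
  expect_identical(effective_kernel_size(3, 2), 5L)
  expect_identical(effective_kernel_size(5, 3), 13L)
  expect_error(effective_kernel_size(0, 1), "positive")
  expect_error(effective_kernel_size(3, 0), "positive")
})

test_that("conv output size counts valid kernel placements", {
  expect_identical(conv_output_size(8, k = 3, d = 2, s = 1, p = 0), 4L)
  expect_identical(conv_output_size(8, k = 3, d = 2, s = 1, p = 2), 8L)
  expect_identical(conv_output_size(8, k = 1, d = 1, s = 1, p = 0), 8L)
  expect_error(conv_output_size(4, k = 5, d = 2), "exceeds")
  # block_spec route, per axis
  sp <- block_spec(kernel = c(3, 5), stride = c(1, 2), dilation = 2,
                   padding = c(2, 0))
  expect_identical(conv_output_size(c(8, 16), sp), c(8L, 4L))
})

test_that("inception block preserves spatial size and sets channels", {
  x <- rand_feature(16, 16, 1)
  inc <- inception_block(1L, "segmentation", out_ch = 8L, branch_ch = 4L)
  y <- block_forward(inc, x)
  expect_equal(dim(y), c(16, 16, 8, 1))
  xc <- rand_feature(16, 16, 12, seed = 2)
  incc <- inception_block(12L, "candidate")
  expect_equal(dim(block_forward(incc, xc)), c(16, 16, 12, 1)) # channel-preserving
})

test_that("dense resample concat resamples by power-of-two and stacks channels", {
  feats <- list(rand_feature(16, 16, 4), rand_feature(8, 8, 6, seed = 2),
                rand_feature(4, 4, 8, seed = 3))
  out <- dense_resample_concat(feats, 3)
  expect_equal(dim(out), c(4, 4, 18, 1))
  # decoder direction: upsample to the finest
  out2 <- dense_resample_concat(feats, 1)
  expect_equal(dim(out2), c(16, 16, 18, 1))
  # single feature returned unchanged
  expect_equal(dense_resample_concat(feats[1], 1), feats[[1]])
  # constant maps stay constant under average pooling
  const <- list(array(3.5, c(8, 8, 1, 1)), array(1, c(4, 4, 1, 1)))
  dc <- dense_resample_concat(const, 2)
  expect_true(all(dc[, , 1, ] == 3.5))
  # non-power-of-two ratios rejected
  bad <- list(rand_feature(12, 12, 2), rand_feature(4, 4, 2, seed = 4))
  expect_error(dense_resample_concat(bad, 2), "power of two")
})

test_that("dilated conv/deconv blocks respect the declared geometry", {
  x <- rand_feature(16, 16, 4)
  blk <- dilated_conv_block(4L, 8L, stride = 1L)
  expect_equal(dim(block_forward(blk, x)), c(16, 16, 8, 1))
  blk2 <- dilated_conv_block(4L, 8L, stride = 2L)
  expect_equal(dim(block_forward(blk2, x)), c(8, 8, 8, 1))
  # deconv: doubles decoder resolution, concat with skip
  dec <- rand_feature(8, 8, 8, seed = 5)
  skip <- rand_feature(16, 16, 4, seed = 6)
  dblk <- dilated_deconv_block(8L, 4L, 4L)
  expect_equal(dim(block_forward(dblk, dec, skip)), c(16, 16, 4, 1))
  bad_skip <- rand_feature(8, 8, 4, seed = 7)
  expect_error(block_forward(dblk, dec, bad_skip), "mismatch")
})

test_that("multires block triples channels at unchanged resolution", {
  for (c0 in c(4L, 8L)) {
    x <- rand_feature(16, 16, c0, seed = c0)
    y <- block_forward(multires_block(c0), x)
    expect_equal(dim(y), c(16, 16, 3 * c0, 1))
  }
  expect_error(block_forward(multires_block(4L), rand_feature(15, 16, 4)),
               "even")
})

test_that("multiscale pool halves resolution and conserves channels", {
  for (m in c(8L, 16L)) {
    x <- rand_feature(16, 16, m, seed = m)
    y <- block_forward(multiscale_pool_block(m), x)
    expect_equal(dim(y), c(8, 8, m, 1))
  }
  expect_error(multiscale_pool_block(6L), "divisible by 4")
  # all four branch output sizes agree by the size algebra
  for (k in 2:5) {
    expect_identical(conv_output_size(16, k = k, s = 2, p = (k - 1) %/% 2), 8L)
  }
})

test_that("blocks are deterministic given fixed weights", {
  x <- rand_feature(16, 16, 4, seed = 9)
  set.seed(31); b1 <- multires_block(4L)
  y1 <- block_forward(b1, x)
  y2 <- block_forward(b1, x)
  expect_identical(y1, y2)
  set.seed(31); b2 <- multires_block(4L)
  expect_identical(block_forward(b2, x), y1)
})
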