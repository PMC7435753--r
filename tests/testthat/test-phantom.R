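# Phantom generator: determinism, ground-truth structure, serialization.

test_that("zero-nodule range gives an empty nodule mask and annotation list", {
  s <- generate_phantom(tiny_params(nodule_count_range = c(0, 0)), seed = 7)
  expect_identical(sum(s$nodule_mask), 0L)
  expect_identical(nrow(s$nodules), 0L)
})

test_that("generation is bit-identical under a fixed seed", {
  p <- tiny_params()
  expect_identical(generate_phantom(p, seed = 3), generate_phantom(p, seed = 3))
})

test_that("nodule mask pixel count matches a brute-force disc rasterizer", {
  p <- tiny_params(nodule_count_range = c(2, 2), nodule_diameter_range = c(9, 9))
  s <- generate_phantom(p, seed = 11)
  expect_identical(nrow(s$nodules), 2L)
  want <- sum(vapply(seq_len(nrow(s$nodules)), function(i) {
    brute_disc_count(p$image_size, s$nodules$center_row[i],
                     s$nodules$center_col[i], s$nodules$diameter[i])
  }, numeric(1)))
  expect_identical(sum(s$nodule_mask), as.integer(want))
})

test_that("masks nest and components equal annotations across seeds", {
  p <- tiny_params()
  for (seed in 1:8) {
    s <- generate_phantom(p, seed = seed)
    expect_true(all(s$nodule_mask <= s$candidate_mask))
    expect_true(all(s$candidate_mask <= s$parenchyma_mask))
    expect_identical(max(label_components(s$nodule_mask)), nrow(s$nodules))
    expect_true(all(s$image$values >= 0 & s$image$values <= 1))
    # annotation centers lie strictly inside the parenchyma
    if (nrow(s$nodules) > 0) {
      idx <- cbind(round(s$nodules$center_row), round(s$nodules$center_col))
      expect_true(all(s$parenchyma_mask[idx] == 1L))
    }
  }
})

test_that("distractors exist outside the parenchyma in the default phantom", {
  s <- generate_phantom(tiny_params(noise_sigma = 0), seed = 21)
  outside_bright <- s$image$values > 0.8 & !s$parenchyma_mask
  expect_gt(sum(outside_bright), 0)
  # and they are excluded from all masks by construction
  expect_identical(sum(s$candidate_mask[!s$parenchyma_mask]), 0L)
})

test_that("dataset derivation is deterministic with distinct per-sample seeds", {
  p <- tiny_params()
  ds <- generate_dataset(5, p, seed = 1)
  expect_length(ds, 5)
  seeds <- vapply(ds, function(s) s$seed, integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  # singleton consistency with the derived seed
  one <- generate_dataset(1, p, seed = 9, negative_fraction = 0)
  derived <- nodulecascade:::phantom_derived_seed(9, 1)
  expect_identical(one[[1]], generate_phantom(p, derived))
})

test_that("negative fraction produces the exact count of empty samples", {
  ds <- generate_dataset(10, tiny_params(), seed = 2, negative_fraction = 0.5)
  n_empty <- sum(vapply(ds, function(s) nrow(s$nodules) == 0, logical(1)))
  expect_identical(n_empty, 5L)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(phantom_params(image_size = 16), "at least 32")
  expect_error(phantom_params(nodule_count_range = c(3, 1)), "non-empty")
  expect_error(phantom_params(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_params(lesion_intensity = 1.2), "\\[0, 1\\]")
})

test_that("a dataset round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, tiny_params(), seed = 4, negative_fraction = 0.34)
  write_phantom_dataset(ds, dir, seed = 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_phantom_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    # image quantized to 16 bits on write
    expect_equal(back[[i]]$image$values,
                 round(ds[[i]]$image$values * 65535) / 65535)
    expect_identical(back[[i]]$parenchyma_mask, ds[[i]]$parenchyma_mask)
    expect_identical(back[[i]]$candidate_mask, ds[[i]]$candidate_mask)
    expect_identical(back[[i]]$nodule_mask, ds[[i]]$nodule_mask)
    expect_equal(back[[i]]$nodules$center_row, ds[[i]]$nodules$center_row)
    expect_equal(back[[i]]$nodules$diameter, ds[[i]]$nodules$diameter)
  }
})
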