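# Metrics: confusion tallies, rates, dice, lesion matching, PR curve.

test_that("confusion counts partition the pixels", {
  gt <- matrix(0L, 4, 4); gt[1, 1:5 %% 5] <- 1L
  gt <- matrix(0L, 4, 4); gt[c(1, 3, 5, 7, 9)] <- 1L
  cc <- confusion_counts(gt, gt)
  expect_equal(cc$TP, 5); expect_equal(cc$FP, 0)
  expect_equal(cc$TN, 11); expect_equal(cc$FN, 0)
  # inverted prediction: no agreement at all
  inv <- 1L - gt
  cc2 <- confusion_counts(inv, gt)
  expect_equal(cc2$TP, 0); expect_equal(cc2$TN, 0)
  expect_equal(cc2$FP + cc2$FN, 16)
  # brute-force enumeration on random grids
  set.seed(1)
  for (i in 1:5) {
    p <- matrix(rbinom(16, 1, 0.5), 4); g <- matrix(rbinom(16, 1, 0.5), 4)
    cc3 <- confusion_counts(p, g)
    want <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (j in 1:16) {
      key <- if (p[j] == 1 && g[j] == 1) "TP" else if (p[j] == 1) "FP"
             else if (g[j] == 1) "FN" else "TN"
      want[key] <- want[key] + 1
    }
    expect_equal(unlist(cc3[c("TP", "FP", "TN", "FN")]),
                 want[c("TP", "FP", "TN", "FN")], ignore_attr = TRUE)
    expect_equal(cc3$TP + cc3$FP + cc3$TN + cc3$FN, 16)
  }
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("rates follow their defining ratios and respect undefinedness", {
  c1 <- confusion_counts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
  expect_equal(accuracy(c1), 0.5)
  c2 <- structure(list(TP = 90, FP = 3, TN = 7, FN = 10),
                  class = "confusion_counts")
  expect_equal(sensitivity(c2), 0.9)
  c3 <- structure(list(TP = 2, FP = 5, TN = 95, FN = 1),
                  class = "confusion_counts")
  expect_equal(specificity(c3), 0.95)
  c0 <- structure(list(TP = 0, FP = 0, TN = 4, FN = 0),
                  class = "confusion_counts")
  expect_true(is.na(sensitivity(c0)))
})

test_that("dice coefficient matches hand counts", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  c_ <- matrix(0L, 4, 4); c_[1:2, 2:3] <- 1L
  expect_equal(dice_coefficient(a, c_), 0.5)
  expect_true(is.na(dice_coefficient(matrix(0L, 2, 2), matrix(0L, 2, 2))))
})

test_that("8-connected labelling agrees with a flood-fill oracle", {
  set.seed(2)
  for (i in 1:6) {
    m <- matrix(rbinom(20 * 20, 1, 0.3), 20)
    got <- label_components(m)
    want <- brute_label8(m)
    expect_identical(max(got), max(want))
    # same partition (labels may be permuted)
    for (k in seq_len(max(got))) {
      expect_true(length(unique(want[got == k])) == 1)
    }
  }
  # diagonal adjacency connects under 8-connectivity
  d <- matrix(0L, 3, 3); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_identical(max(label_components(d)), 1L)
})

test_that("labelling agrees with EBImage on diagonal-free shapes", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:5] <- 1L; m[10:13, 8:10] <- 1L; m[17, 15:18] <- 1L
  expect_identical(max(label_components(m)),
                   as.integer(max(EBImage::bwlabel(m))))
})

test_that("lesion matching hits by centroid distance", {
  L <- 32
  ann <- data.frame(id = 1:2, center_row = c(8, 24), center_col = c(8, 22),
                    diameter = c(9, 7))
  mask <- matrix(0L, L, L)
  for (i in 1:2) {
    px <- nodulecascade:::disc_pixels(L, ann$center_row[i], ann$center_col[i],
                                      ann$diameter[i])
    mask[px] <- 1L
  }
  hit <- match_lesions(mask, ann)
  expect_equal(hit$TP, 2); expect_equal(hit$FP, 0); expect_equal(hit$FN, 0)
  # empty prediction: all annotations missed
  miss <- match_lesions(matrix(0L, L, L), ann)
  expect_equal(miss$FN, 2); expect_equal(miss$TP, 0)
  # a component centered 1 px off a diameter-9 annotation still hits
  one <- data.frame(id = 1, center_row = 16, center_col = 16, diameter = 9)
  shifted <- matrix(0L, L, L)
  shifted[nodulecascade:::disc_pixels(L, 17, 16, 5)] <- 1L
  expect_equal(match_lesions(shifted, one)$TP, 1)
  # far-away component is a false positive
  far <- matrix(0L, L, L)
  far[nodulecascade:::disc_pixels(L, 28, 4, 5)] <- 1L
  cc <- match_lesions(far, one)
  expect_equal(cc$FP, 1); expect_equal(cc$FN, 1)
  # each annotation claims at most one component
  both <- matrix(0L, L, L)
  both[nodulecascade:::disc_pixels(L, 13, 14, 4)] <- 1L
  both[nodulecascade:::disc_pixels(L, 19, 18, 4)] <- 1L
  cc2 <- match_lesions(both, one)
  expect_equal(cc2$TP, 1); expect_equal(cc2$FP, 1)
  # sub-nodule-size specks are not lesions
  speck <- matrix(0L, L, L); speck[4, 4] <- 1L; speck[28, 28:29] <- 1L
  cc3 <- match_lesions(speck, one)
  expect_equal(cc3$FP, 0); expect_equal(cc3$FN, 1)
})

test_that("IoU criterion accepts overlapping and rejects grazing lesions", {
  one <- data.frame(id = 1, center_row = 16, center_col = 16, diameter = 9)
  good <- matrix(0L, 32, 32)
  good[nodulecascade:::disc_pixels(32, 16, 16, 9)] <- 1L
  expect_equal(match_lesions(good, one, criterion = "iou")$TP, 1)
  graze <- matrix(0L, 32, 32)
  graze[nodulecascade:::disc_pixels(32, 20, 20, 3)] <- 1L
  expect_equal(match_lesions(graze, one, criterion = "iou")$TP, 0)
})

test_that("PR curve: perfect separation gives AUC 1 and recall is
           monotone in the threshold", {
  p <- tiny_params()
  ds <- lapply(1:4, function(i) generate_phantom(p, seed = 30 + i))
  maps <- lapply(ds, function(s) s$nodule_mask * 1.0)
  anns <- lapply(ds, function(s) s$nodules)
  pr <- pr_curve(maps, anns)
  expect_equal(pr$auc, 1.0)
  expect_true(all(pr$points$precision == 1))
  # graded detector: each lesion at its own confidence level, so lesions
  # drop out one by one and recall never increases as the threshold rises
  set.seed(5)
  noisy <- lapply(maps, function(m) {
    lab <- label_components(m)
    amp <- runif(max(lab) + 1, 0.2, 1)
    out <- m * 0
    if (max(lab) > 0) out[lab > 0] <- amp[lab[lab > 0]]
    out
  })
  pr2 <- pr_curve(noisy, anns)
  rec <- pr2$points$recall[!is.na(pr2$points$recall)]
  expect_true(all(diff(rec) <= 1e-12))
  # AUC equals an independent trapezoidal re-integration of the points
  pts <- pr2$points[!is.na(pr2$points$recall), ]
  ord <- order(pts$recall, -pts$threshold)
  r <- c(0, pts$recall[ord]); pp <- c(pts$precision[ord][1], pts$precision[ord])
  expect_equal(pr2$auc, sum(diff(r) * (pp[-1] + head(pp, -1)) / 2))
  expect_error(pr_curve(maps, anns, thresholds = c(0.5, 0.2)), "sorted")
})
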