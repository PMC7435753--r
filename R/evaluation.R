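## Detection metrics at pixel and lesion level: confusion tallies,
## accuracy / sensitivity / specificity, the dice coefficient,
## connected-component lesion matching against annotation tables, and
## the lesion-level precision-recall curve with trapezoidal AUC.

#' Confusion counts from binary grids
#'
#' @param pred_bin,gt_bin binary grids (0/1 or logical) of identical
#'   dimensions.
#' @return object of class `"confusion_counts"`: list of `TP`, `FP`,
#'   `TN`, `FN`; the four counts partition the pixels.
#' @export
confusion_counts <- function(pred_bin, gt_bin) {
  if (!identical(dim(pred_bin), dim(gt_bin))) {
    stop("confusion_counts: dimension mismatch")
  }
  p <- as.vector(pred_bin); g <- as.vector(gt_bin)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop("confusion_counts: inputs must be binary")
  }
  new_confusion(TP = sum(p == 1 & g == 1), FP = sum(p == 1 & g == 0),
                TN = sum(p == 0 & g == 0), FN = sum(p == 0 & g == 1))
}

new_confusion <- function(TP, FP, TN, FN) {
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 TN = as.numeric(TN), FN = as.numeric(FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g TN=%g FN=%g\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

rate <- function(num, den) if (den > 0) num / den else NA_real_

#' Accuracy, sensitivity and specificity
#'
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`, `Sens = TP / (TP + FN)`,
#' `Spec = TN / (TN + FP)`. A zero denominator yields `NA` (undefined),
#' never a silent 0.
#'
#' @param c a [confusion_counts()] object.
#' @return scalar in `[0, 1]`, or `NA` when undefined.
#' @export
accuracy <- function(c) rate(c$TP + c$TN, c$TP + c$FP + c$TN + c$FN)

#' @rdname accuracy
#' @export
sensitivity <- function(c) rate(c$TP, c$TP + c$FN)

#' @rdname accuracy
#' @export
specificity <- function(c) rate(c$TN, c$TN + c$FP)

precision_of <- function(c) rate(c$TP, c$TP + c$FP)

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; `NA` when both masks are empty.
#'
#' @param pred_bin,gt_bin binary grids of identical dimensions.
#' @return scalar in `[0, 1]`, or `NA` when undefined.
#' @export
dice_coefficient <- function(pred_bin, gt_bin) {
  if (!identical(dim(pred_bin), dim(gt_bin))) {
    stop("dice_coefficient: dimension mismatch")
  }
  p <- as.vector(pred_bin) > 0; g <- as.vector(gt_bin) > 0
  denom <- sum(p) + sum(g)
  if (denom == 0) return(NA_real_)
  2 * sum(p & g) / denom
}

#' 8-connected component labelling
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background), labelled
#'   1..k in scan order.
#' @export
label_components <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  cpp_label8(m)
}

#' Match predicted lesions against nodule annotations
#'
#' Connected components (8-connectivity) of the predicted mask are
#' matched to annotations greedily, nearest pair first. With the
#' `"centroid"` criterion a component hits an annotation when its
#' centroid lies within `diameter / 2` of the annotation center; with
#' `"iou"` the component must overlap the annotation's rasterized disc
#' with intersection-over-union at least `iou_threshold`. Each
#' annotation claims at most one component. Unmatched components are
#' false positives, unmatched annotations false negatives; lesion-level
#' true negatives are not defined (TN = 0).
#'
#' Components smaller than `min_area` pixels are discarded before
#' matching: pulmonary nodules are by definition at least 3 px across,
#' and no disc of that diameter covers fewer than `min_area = 7` pixels,
#' so smaller components cannot be lesions.
#'
#' @param pred_mask binary matrix.
#' @param annotations data frame with columns `center_row`, `center_col`,
#'   `diameter` (pixels).
#' @param criterion `"centroid"` (default) or `"iou"`.
#' @param iou_threshold minimum IoU for the `"iou"` criterion.
#' @param min_area smallest component size (pixels) considered a lesion.
#' @return a [confusion_counts()] object (lesion-level; TN = 0).
#' @export
match_lesions <- function(pred_mask, annotations,
                          criterion = c("centroid", "iou"),
                          iou_threshold = 0.25, min_area = 7L) {
  criterion <- match.arg(criterion)
  lab <- label_components(pred_mask)
  if (max(lab) > 0 && min_area > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  ncomp <- max(lab)
  nann <- nrow(annotations)
  if (ncomp == 0 || nann == 0) {
    return(new_confusion(TP = 0, FP = ncomp, TN = 0, FN = nann))
  }
  pairs <- NULL
  if (criterion == "centroid") {
    cent <- t(vapply(seq_len(ncomp), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
    for (a in seq_len(nann)) {
      d <- sqrt((cent[, 1] - annotations$center_row[a])^2 +
                (cent[, 2] - annotations$center_col[a])^2)
      hit <- which(d <= annotations$diameter[a] / 2)
      if (length(hit)) {
        pairs <- rbind(pairs, cbind(comp = hit, ann = a, score = d[hit]))
      }
    }
  } else {
    L1 <- nrow(pred_mask); L2 <- ncol(pred_mask)
    for (a in seq_len(nann)) {
      px <- disc_pixels(max(L1, L2), annotations$center_row[a],
                        annotations$center_col[a], annotations$diameter[a])
      px <- px[px[, 1] <= L1 & px[, 2] <= L2, , drop = FALSE]
      disc <- matrix(FALSE, L1, L2); disc[px] <- TRUE
      for (k in seq_len(ncomp)) {
        comp <- lab == k
        iou <- sum(comp & disc) / sum(comp | disc)
        if (iou >= iou_threshold) {
          pairs <- rbind(pairs, cbind(comp = k, ann = a, score = -iou))
        }
      }
    }
  }
  tp <- 0
  used_comp <- logical(ncomp); used_ann <- logical(nann)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, "score"]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      ci <- pairs[r, "comp"]; ai <- pairs[r, "ann"]
      if (used_comp[ci] || used_ann[ai]) next
      used_comp[ci] <- TRUE; used_ann[ai] <- TRUE
      tp <- tp + 1
    }
  }
  new_confusion(TP = tp, FP = sum(!used_comp), TN = 0, FN = sum(!used_ann))
}

#' Lesion-level precision-recall curve
#'
#' Binarizes each probability map at every threshold, matches lesions
#' against the annotations, and aggregates TP/FP/FN over the dataset.
#' Precision with no detections is taken as 1. The AUC is the
#' trapezoidal integral of precision over recall, anchored at recall 0
#' with the precision of the most conservative threshold.
#'
#' @param prob_maps list of probability matrices in `[0, 1]`.
#' @param annotations_list list of annotation data frames, parallel to
#'   `prob_maps`.
#' @param thresholds increasing vector of thresholds in (0, 1).
#' @param criterion lesion hit criterion, see [match_lesions()].
#' @return object of class `"pr_curve"`: data frame `points`
#'   (threshold, TP, FP, FN, precision, recall) and scalar `auc`.
#' @export
pr_curve <- function(prob_maps, annotations_list,
                     thresholds = seq(0.05, 0.95, by = 0.05),
                     criterion = "centroid") {
  stopifnot(length(prob_maps) == length(annotations_list),
            length(prob_maps) >= 1)
  if (any(thresholds <= 0 | thresholds >= 1) || is.unsorted(thresholds)) {
    stop("thresholds must be sorted and lie in (0, 1)")
  }
  pts <- do.call(rbind, lapply(thresholds, function(th) {
    tot <- c(TP = 0, FP = 0, FN = 0)
    for (i in seq_along(prob_maps)) {
      cc <- match_lesions(prob_maps[[i]] >= th, annotations_list[[i]],
                          criterion = criterion)
      tot <- tot + c(cc$TP, cc$FP, cc$FN)
    }
    data.frame(threshold = th, TP = tot[1], FP = tot[2], FN = tot[3],
               precision = if (tot[1] + tot[2] > 0) tot[1] / (tot[1] + tot[2]) else 1,
               recall = if (tot[1] + tot[3] > 0) tot[1] / (tot[1] + tot[3]) else NA_real_)
  }))
  rownames(pts) <- NULL
  ok <- !is.na(pts$recall)
  auc <- if (any(ok)) {
    ord <- order(pts$recall[ok], -pts$threshold[ok])
    r <- pts$recall[ok][ord]; p <- pts$precision[ok][ord]
    r <- c(0, r); p <- c(p[1], p)
    sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  } else {
    NA_real_
  }
  structure(list(points = pts, auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Evaluate a cascade on a phantom dataset
#'
#' Runs inference on every sample and reports pixel-level metrics of the
#' nodule map against the nodule ground truth, lesion-level metrics via
#' [match_lesions()], the mean dice coefficient over positive samples,
#' and the lesion-level PR curve.
#'
#' @param cascade a trained `nodule_cascade`.
#' @param samples list of phantom samples.
#' @param threshold binarization threshold for the headline metrics.
#' @param thresholds PR-curve threshold sweep.
#' @return object of class `"cascade_evaluation"`.
#' @export
evaluate_cascade <- function(cascade, samples, threshold = 0.5,
                             thresholds = seq(0.05, 0.95, by = 0.05)) {
  prob_maps <- lapply(samples, function(s) {
    drop_ch(cascade_forward(cascade, s$image$values)$nodule_prob)
  })
  pix <- new_confusion(0, 0, 0, 0)
  les <- new_confusion(0, 0, 0, 0)
  dices <- numeric(0)
  for (i in seq_along(samples)) {
    pb <- (prob_maps[[i]] >= threshold) * 1L
    cc <- confusion_counts(pb, samples[[i]]$nodule_mask)
    for (f in names(pix)) pix[[f]] <- pix[[f]] + cc[[f]]
    lc <- match_lesions(pb, samples[[i]]$nodules)
    for (f in names(les)) les[[f]] <- les[[f]] + lc[[f]]
    if (sum(samples[[i]]$nodule_mask) > 0) {
      dices <- c(dices, dice_coefficient(pb, samples[[i]]$nodule_mask))
    }
  }
  pr <- pr_curve(prob_maps, lapply(samples, function(s) s$nodules),
                 thresholds = thresholds)
  structure(list(
    pixel = list(counts = pix, accuracy = accuracy(pix),
                 sensitivity = sensitivity(pix), specificity = specificity(pix)),
    lesion = list(counts = les, sensitivity = sensitivity(les),
                  precision = precision_of(les)),
    mean_dice = if (length(dices)) mean(dices) else NA_real_,
    pr = pr,
    threshold = threshold,
    n = length(samples)
  ), class = "cascade_evaluation")
}

drop_ch <- function(x) {
  d <- dim(x)
  if (length(d) > 2) matrix(x, d[1], d[2]) else x
}

#' @export
print.cascade_evaluation <- function(x, ...) {
  cat("<cascade_evaluation>", x$n, "samples, threshold", x$threshold, "\n")
  cat(sprintf("  pixel:  acc %.4f  sens %.4f  spec %.4f\n",
              x$pixel$accuracy, x$pixel$sensitivity, x$pixel$specificity))
  cat(sprintf("  lesion: sens %.4f  prec %.4f  (TP %g FP %g FN %g)\n",
              x$lesion$sensitivity, x$lesion$precision,
              x$lesion$counts$TP, x$lesion$counts$FP, x$lesion$counts$FN))
  cat(sprintf("  mean dice %.4f   lesion PR-AUC %.4f\n", x$mean_dice, x$pr$auc))
  invisible(x)
}
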