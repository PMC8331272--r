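#' Dice overlap between two binary masks
#'
#' `2|X ∩ Y| / (|X| + |Y|)`: 1 for identical nonempty masks, 0 for
#' disjoint ones.
#'
#' @param x,y Logical (or 0/1) arrays of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(x, y) {
  x <- unclass(x) > 0; y <- unclass(y) > 0
  check_shape_equal(x, y, "masks")
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) {
    stop_mcdreg("Dice is undefined for two empty masks",
                "mcdreg_degenerate_error")
  }
  2 * sum(x & y) / (nx + ny)
}

#' Per-region Dice scores for label volumes
#'
#' Computes the Dice overlap of each region label between two label
#' volumes (e.g. warped source labels vs target labels) and their mean, the
#' standard accuracy summary for anatomical registration.
#'
#' @param x,y `label_volume`s of equal shape.
#' @param labels Region labels to score; default all nonzero labels present
#'   in either volume.
#' @return A tibble with columns `label` and `dice`; the mean over regions
#'   is `mean(out$dice)`.
#' @export
dice_labels <- function(x, y, labels = NULL) {
  x <- as_label_volume(x); y <- as_label_volume(y)
  check_shape_equal(x, y, "label volumes")
  if (is.null(labels)) labels <- union(label_ids(x), label_ids(y))
  labels <- sort(as.integer(labels))
  tibble::tibble(
    label = labels,
    dice = vapply(labels, function(l) dice(unclass(x) == l, unclass(y) == l),
                  numeric(1))
  )
}

#' Per-voxel correctness map of a registration
#'
#' Marks each nonbackground target voxel as correct when the warped source
#' label equals the target label, the "ground truth vs prediction" map that
#' the uncertainty-quality metrics are computed against. Background voxels
#' (target label 0) are excluded (`NA`).
#'
#' @param warped_labels Source labels warped through the predicted (mean)
#'   displacement field.
#' @param target_labels Target `label_volume`.
#' @return 3D array: `TRUE` correct, `FALSE` incorrect, `NA` background.
#' @export
correctness_map <- function(warped_labels, target_labels) {
  w <- as_label_volume(warped_labels); t <- as_label_volume(target_labels)
  check_shape_equal(w, t, "label volumes")
  domain <- unclass(t) > 0
  if (!any(domain)) {
    stop_mcdreg("all-background target: empty evaluation domain",
                "mcdreg_degenerate_error")
  }
  out <- array(NA, dim = dim(t))
  out[domain] <- unclass(w)[domain] == unclass(t)[domain]
  out
}

#' Confusion counts of an uncertainty estimate at one threshold
#'
#' A voxel is "uncertain" when its normalized uncertainty strictly exceeds
#' the threshold `T` (so `T = 1` flags nothing). Desirable cases are
#' uncertain-and-incorrect (TP) and certain-and-correct (TN); the
#' undesirable ones are uncertain-and-correct (FP) and
#' certain-and-incorrect (FN). Counts are over the nonbackground evaluation
#' domain of the correctness map.
#'
#' @param correct Correctness map from [correctness_map()] (`NA` = excluded).
#' @param unc Normalized scalar uncertainty map in \[0, 1\], same shape.
#' @param threshold Threshold `T` in \[0, 1\].
#' @return An `uncertainty_confusion` list: `tp`, `tn`, `fp`, `fn`,
#'   `threshold`.
#' @export
uncertainty_confusion <- function(correct, unc, threshold) {
  if (length(threshold) != 1 || threshold < 0 || threshold > 1) {
    stop_mcdreg("threshold must be a single value in [0, 1]",
                "mcdreg_argument_error")
  }
  check_shape_equal(correct, unc, "correctness and uncertainty maps")
  keep <- !is.na(correct)
  cor <- correct[keep] > 0
  unsure <- unc[keep] > threshold
  structure(list(tp = sum(unsure & !cor), tn = sum(!unsure & cor),
                 fp = sum(unsure & cor), fn = sum(!unsure & !cor),
                 threshold = threshold),
            class = "uncertainty_confusion")
}

#' Uncertainty-quality metrics
#'
#' `npv()` — among voxels the model is *certain* about, the fraction
#' registered correctly, `TN / (TN + FN)`. `tpr()` — among *incorrectly*
#' registered voxels, the fraction flagged uncertain, `TP / (TP + FN)`.
#' `ua()` — overall fraction of desirable cases,
#' `(TP + TN) / (TP + TN + FP + FN)`. Each returns `NA` when its
#' denominator is zero (reported as missing rather than fabricating a
#' value at extreme thresholds).
#'
#' @param conf An [uncertainty_confusion()].
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
npv <- function(conf) {
  d <- conf$tn + conf$fn
  if (d == 0) NA_real_ else conf$tn / d
}

#' @rdname npv
#' @export
tpr <- function(conf) {
  d <- conf$tp + conf$fn
  if (d == 0) NA_real_ else conf$tp / d
}

#' @rdname npv
#' @export
ua <- function(conf) {
  d <- conf$tp + conf$tn + conf$fp + conf$fn
  if (d == 0) NA_real_ else (conf$tp + conf$tn) / d
}

#' Sweep the uncertainty threshold
#'
#' Evaluates the confusion counts and NPV/TPR/UA at each threshold
#' (default grid 0, 0.1, ..., 1.0). TPR is non-increasing in the threshold
#' by construction: raising `T` can only shrink the uncertain set.
#'
#' @inheritParams uncertainty_confusion
#' @param thresholds Numeric vector of thresholds in \[0, 1\].
#' @return An `uncertainty_sweep` tibble with columns `threshold`, `tp`,
#'   `tn`, `fp`, `fn`, `npv`, `tpr`, `ua`; plot with [autoplot()].
#' @export
threshold_sweep <- function(correct, unc, thresholds = seq(0, 1, by = 0.1)) {
  rows <- lapply(thresholds, function(th) {
    cf <- uncertainty_confusion(correct, unc, th)
    tibble::tibble(threshold = th, tp = cf$tp, tn = cf$tn, fp = cf$fp,
                   fn = cf$fn, npv = npv(cf), tpr = tpr(cf), ua = ua(cf))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("uncertainty_sweep", class(out))
  out
}

#' Evaluate a trained registration model on labeled pairs
#'
#' For each held-out pair: Monte Carlo inference, warping of the source
#' image and labels through the mean field, per-region Dice, folding count
#' of the mean field (over nonbackground target voxels), and mean
#' normalized uncertainty. Uncertainty is normalized by set-wide min/max
#' statistics before thresholding, and a pooled NPV/TPR/UA sweep is
#' computed over all pairs.
#'
#' @param net A `bfcnm` network or `bfcnm_fit`.
#' @param pairs List of pairs, each a list with `S`, `T`, `S_labels`,
#'   `T_labels` (e.g. from [make_pair()]).
#' @param M Monte Carlo samples per pair (default 48).
#' @param seed Master seed for sampling.
#' @param thresholds Threshold grid for the sweep.
#' @return List with `per_pair` (tibble: pair, mean Dice registered and
#'   unregistered, folding count, mean nonbackground uncertainty),
#'   `dice_regions`
#'   (tibble of per-region scores), `sweep` (pooled `uncertainty_sweep`),
#'   and `stats` (the normalization statistics used).
#' @export
evaluate_registration <- function(net, pairs, M = 48, seed = 1L,
                                  thresholds = seq(0, 1, by = 0.1)) {
  if (inherits(net, "bfcnm_fit")) net <- net$network
  seeds <- derive_seeds(seed, length(pairs))
  summaries <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    summaries[[i]] <- mc_summary(net, p$S, p$T, M = M, seed = seeds[i])
  }
  stats <- uncertainty_stats(summaries)

  per_pair <- list(); regions <- list()
  corrects <- list(); uncs <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    mu <- summaries[[i]]$mu
    warped_lab <- warp_labels(p$S_labels, mu)
    dt <- dice_labels(warped_lab, p$T_labels)
    d0 <- dice_labels(p$S_labels, p$T_labels)
    jac <- jacobian_determinant(mu)
    nfold <- folding_count(jac, mask = p$T_labels)
    unc <- uncertainty_map(summaries[[i]], stats)
    cm <- correctness_map(warped_lab, p$T_labels)
    corrects[[i]] <- cm; uncs[[i]] <- unc
    per_pair[[i]] <- tibble::tibble(
      pair = i, dice = mean(dt$dice), dice_unregistered = mean(d0$dice),
      folding = nfold,
      mean_uncertainty = mean(unc[unclass(p$T_labels) > 0]))
    regions[[i]] <- dplyr::mutate(dt, pair = i)
  }
  correct_all <- unlist(lapply(corrects, as.vector))
  unc_all <- unlist(lapply(uncs, as.vector))
  sweep <- threshold_sweep(array(correct_all, dim = c(length(correct_all), 1, 1)),
                           array(unc_all, dim = c(length(unc_all), 1, 1)),
                           thresholds)
  list(per_pair = dplyr::bind_rows(per_pair),
       dice_regions = dplyr::bind_rows(regions),
       sweep = sweep, stats = stats)
}
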