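test_that("dice matches hand-computed overlaps and is symmetric", {
  sh <- c(4, 4, 4)
  x <- array(FALSE, sh); y <- array(FALSE, sh)
  x[1:4] <- TRUE; y[3:8] <- TRUE   # |X| = 4, |Y| = 6, overlap = 2
  expect_equal(dice(x, y), 0.4)
  expect_equal(dice(y, x), 0.4)
  expect_equal(dice(x, x), 1)
  z <- array(FALSE, sh); z[30:33] <- TRUE
  expect_equal(dice(x, z), 0)
  expect_error(dice(array(FALSE, sh), array(FALSE, sh)),
               class = "mcdreg_degenerate_error")
})

test_that("per-region dice covers all labels and averages correctly", {
  set.seed(91)
  a <- as_label_volume(array(sample(0:3, 216, replace = TRUE), dim = c(6, 6, 6)))
  b <- as_label_volume(array(sample(0:3, 216, replace = TRUE), dim = c(6, 6, 6)))
  tab <- dice_labels(a, b)
  expect_setequal(tab$label, 1:3)
  for (l in 1:3) {
    expect_equal(tab$dice[tab$label == l],
                 dice(unclass(a) == l, unclass(b) == l))
  }
  expect_equal(mean(dice_labels(a, a)$dice), 1)
})

test_that("correctness map marks mismatches over the nonbackground domain", {
  set.seed(92)
  t <- array(sample(1:3, 64, replace = TRUE), dim = c(4, 4, 4))
  t[1:8] <- 0L  # background
  w <- t
  flip <- c(12, 20, 33)  # three nonbackground voxels made wrong
  w[flip] <- (t[flip] %% 3L) + 1L
  cm <- correctness_map(as_label_volume(w), as_label_volume(t))
  expect_true(all(is.na(cm[1:8])))
  expect_identical(sum(cm == FALSE, na.rm = TRUE), 3L)
  expect_identical(sum(!is.na(cm)), 56L)

  cm_perfect <- correctness_map(as_label_volume(t), as_label_volume(t))
  expect_true(all(cm_perfect[t > 0] == TRUE))
  expect_error(correctness_map(as_label_volume(w),
                               as_label_volume(array(0L, dim = c(4, 4, 4)))),
               class = "mcdreg_degenerate_error")
})

test_that("uncertainty confusion matches exhaustive enumeration", {
  # 10-voxel toy with hand-assigned correctness and uncertainty
  correct <- array(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE,
                     FALSE, TRUE), dim = c(10, 1, 1))
  unc <- array(c(0.05, 0.95, 0.80, 0.10, 0.30, 0.95, 0.60, 0.20, 0.01, 0.44),
               dim = c(10, 1, 1))
  for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    cf <- uncertainty_confusion(correct, unc, th)
    o <- oracle_confusion(correct, unc, th)
    expect_identical(c(tp = cf$tp, tn = cf$tn, fp = cf$fp, fn = cf$fn), o)
    expect_identical(cf$tp + cf$tn + cf$fp + cf$fn, 10L)
  }
  # threshold endpoints
  cf1 <- uncertainty_confusion(correct, unc, 1)
  expect_identical(cf1$tp + cf1$fp, 0L)          # nothing uncertain at T = 1
  cf0 <- uncertainty_confusion(correct, unc, 0)
  expect_identical(cf0$tn + cf0$fn, 0L)          # all unc > 0: nothing certain
  expect_error(uncertainty_confusion(correct, unc, 1.5),
               class = "mcdreg_argument_error")
})

test_that("NPV, TPR and UA are the stated ratios with NA at empty denominators", {
  cf <- structure(list(tp = 2L, tn = 3L, fp = 1L, fn = 1L, threshold = 0.5),
                  class = "uncertainty_confusion")
  expect_equal(npv(cf), 3 / 4)
  expect_equal(tpr(cf), 2 / 3)
  expect_equal(ua(cf), 5 / 7)
  perfect <- structure(list(tp = 4L, tn = 6L, fp = 0L, fn = 0L, threshold = 0.5),
                       class = "uncertainty_confusion")
  expect_equal(ua(perfect), 1)
  expect_equal(tpr(perfect), 1)
  none_cert <- structure(list(tp = 5L, tn = 0L, fp = 5L, fn = 0L, threshold = 0),
                         class = "uncertainty_confusion")
  expect_true(is.na(npv(none_cert)))
})

test_that("threshold sweep reproduces brute force and TPR never increases", {
  set.seed(93)
  correct <- array(sample(c(TRUE, FALSE, NA), 100, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)), dim = c(100, 1, 1))
  unc <- array(runif(100), dim = c(100, 1, 1))
  sweep <- threshold_sweep(correct, unc)
  expect_identical(nrow(sweep), 11L)
  for (r in seq_len(nrow(sweep))) {
    o <- oracle_confusion(correct, unc, sweep$threshold[r])
    expect_identical(c(tp = sweep$tp[r], tn = sweep$tn[r],
                       fp = sweep$fp[r], fn = sweep$fn[r]), o)
  }
  n_uncertain <- sweep$tp + sweep$fp
  expect_true(all(diff(n_uncertain) <= 0))
  expect_true(all(diff(sweep$tpr[!is.na(sweep$tpr)]) <= 1e-12))

  # constant uncertainty: exactly two distinct confusion rows
  unc_const <- array(0.35, dim = c(100, 1, 1))
  sw2 <- threshold_sweep(correct, unc_const)
  expect_identical(nrow(unique(sw2[, c("tp", "tn", "fp", "fn")])), 2L)
})

test_that("sweep tidies to long format and plots", {
  set.seed(94)
  correct <- array(runif(50) > 0.4, dim = c(50, 1, 1))
  unc <- array(runif(50), dim = c(50, 1, 1))
  sw <- threshold_sweep(correct, unc)
  long <- tidy(sw)
  expect_setequal(unique(long$metric), c("npv", "tpr", "ua"))
  expect_identical(nrow(long), 33L)
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})
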