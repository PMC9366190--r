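test_that("confusion matrices count by the stated orientation", {
  cm <- confusion_matrix(c("abnormal", "normal"), c("abnormal", "normal"))
  expect_equal(cm$tp, 1); expect_equal(cm$tn, 1)
  expect_equal(cm$fp, 0); expect_equal(cm$fn, 0)
  cm2 <- confusion_matrix(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(cm2$fp, 5)
  expect_error(confusion_matrix(TRUE, c(TRUE, FALSE)), "lengths differ")
  # self-consistency: counts rebuild the same matrix
  set.seed(1)
  p <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  cm3 <- confusion_matrix(p, t)
  expect_identical(confusion_counts(cm3$tp, cm3$fp, cm3$fn, cm3$tn)[1:4],
                   cm3[1:4])
})

test_that("sens/spec/acc and kappa reproduce the published cohort tables", {
  # each row: counts and the printed sens/spec/acc/kappa at 3 decimals
  cases <- list(
    list(c(443, 36, 49, 702), c(0.900, 0.951, 0.931, 0.855)),  # CV video
    list(c(87, 7, 6, 105),    c(0.935, 0.938, 0.937, 0.872)),  # CV study
    list(c(276, 45, 30, 477), c(0.902, 0.914, 0.909, 0.808)),  # test video
    list(c(57, 4, 5, 72),     c(0.919, 0.947, 0.935, 0.868)),  # test study
    list(c(131, 23, 37, 91),  c(0.780, 0.798, 0.787, 0.567)),  # mid-LVEF CV video
    list(c(33, 5, 4, 5),      c(0.892, 0.500, 0.809, 0.407)),  # mid-LVEF CV study
    list(c(126, 23, 26, 71),  c(0.829, 0.755, 0.801, 0.581)),  # mid-LVEF test video
    list(c(32, 3, 1, 5),      c(0.970, 0.625, 0.902, 0.657)))  # mid-LVEF test study
  for (cs in cases) {
    cm <- confusion_counts(cs[[1]][1], cs[[1]][2], cs[[1]][3], cs[[1]][4])
    s <- sens_spec_acc(cm)
    k <- cohens_kappa(cm)
    expect_equal(round(s$sensitivity, 3), cs[[2]][1])
    expect_equal(round(s$specificity, 3), cs[[2]][2])
    expect_equal(round(s$accuracy, 3), cs[[2]][3])
    expect_equal(round(k$kappa, 3), cs[[2]][4])
  }
  # expert comparisons report kappa only
  expect_equal(round(cohens_kappa(confusion_counts(37, 5, 4, 54))$kappa, 3),
               0.815)
  expect_equal(round(cohens_kappa(confusion_counts(33, 9, 4, 54))$kappa, 3),
               0.729)
  # the 95% CI of the per-video cross-validation kappa
  ci <- cohens_kappa(confusion_counts(443, 36, 49, 702))$ci
  expect_equal(round(ci, 2), c(0.83, 0.89))
  # bundled reference counts match the frozen values
  ref <- clinical_reference_counts()
  cv <- ref[ref$cohort == "cross_validation" & ref$level == "per_video" &
              ref$stratum == "all", ]
  expect_equal(unlist(cv[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(443, 36, 49, 702))
})

test_that("kappa behaves under relabeling, independence and growing N", {
  cm <- confusion_counts(40, 10, 5, 45)
  k1 <- cohens_kappa(cm)$kappa
  # swapping the positive class leaves kappa unchanged
  k2 <- cohens_kappa(confusion_counts(45, 5, 10, 40))$kappa
  expect_equal(k1, k2)
  expect_equal(cohens_kappa(confusion_counts(10, 0, 0, 10))$kappa, 1)
  # marginally independent raters give kappa ~ 0 (permutation check)
  set.seed(42)
  ks <- replicate(60, {
    p <- sample(rep(c(TRUE, FALSE), c(30, 70)))
    t <- sample(rep(c(TRUE, FALSE), c(40, 60)))
    cohens_kappa(confusion_matrix(p, t))$kappa
  })
  expect_lt(abs(mean(ks)), 0.05)
  # CI width shrinks as 1/sqrt(N) at fixed po, pe
  w1 <- diff(cohens_kappa(confusion_counts(40, 10, 5, 45))$ci)
  w2 <- diff(cohens_kappa(confusion_counts(160, 40, 20, 180))$ci)
  expect_equal(w2 / w1, 0.5, tolerance = 1e-9)
  expect_error(cohens_kappa(confusion_counts(5, 0, 0, 0)), "degenerate")
  expect_error(sens_spec_acc(confusion_counts(0, 5, 0, 5))$sensitivity,
               NA)  # returns NA, no error
  expect_true(is.na(sens_spec_acc(confusion_counts(0, 5, 0, 5))$sensitivity))
})

test_that("per-view re-binning reports each view separately", {
  set.seed(7)
  n <- 240
  view <- rep(0:5, each = 40)
  truth <- rep(c(TRUE, FALSE), 120)
  pred <- truth
  flip <- sample(n, 30)
  pred[flip] <- !pred[flip]
  reps <- rebin_by_view(pred, truth, view)
  expect_length(reps, 6L)
  expect_named(reps, view_table()$wall)
  accs <- vapply(reps, `[[`, numeric(1), "accuracy")
  expect_equal(mean(accs), 1 - 30 / 240, tolerance = 0.05)
  # only one view present: the other five are flagged empty
  reps2 <- rebin_by_view(pred[view == 2], truth[view == 2],
                         view[view == 2])
  expect_length(attr(reps2, "empty_views"), 5L)
  expect_false("inferior" %in% attr(reps2, "empty_views"))
  expect_error(rebin_by_view(pred, truth, rep(NA, n)), "missing view")
  # random predictions give near-zero kappa per view
  set.seed(8)
  pred_r <- sample(c(TRUE, FALSE), n, replace = TRUE)
  reps3 <- rebin_by_view(pred_r, truth, view)
  kaps <- vapply(reps3, `[[`, numeric(1), "kappa")
  expect_lt(max(abs(kaps)), 0.35)
  expect_lt(abs(mean(kaps)), 0.15)
})

test_that("LVEF strata use the documented boundary convention", {
  lvef <- c(0.30, 0.40, 0.50, 0.60, 0.70)
  pred <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  truth <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  reps <- stratify_by_lvef(pred, truth, lvef)
  expect_named(reps, c("lvef_lt_40", "lvef_40_60", "lvef_gt_60"))
  # 0.40 and 0.60 both land in the middle bin
  expect_equal(reps$lvef_40_60$cm$tp + reps$lvef_40_60$cm$fp +
                 reps$lvef_40_60$cm$fn + reps$lvef_40_60$cm$tn, 3)
  expect_error(stratify_by_lvef(pred, truth, c(0.3, 0.4, 0.5, 0.6, 1.7)),
               "lvef")
  # the mid-LVEF published counts give the printed accuracy
  s <- sens_spec_acc(confusion_counts(131, 23, 37, 91))
  expect_equal(round(s$accuracy, 3), 0.787)
})

test_that("the two-proportion z-test matches its closed form", {
  r0 <- two_proportion_z(30, 100, 30, 100)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  # the published cohort abnormal-video proportions are not different
  r1 <- two_proportion_z(492, 1230, 306, 828)
  expect_gt(r1$p, 0.05)
  r2 <- two_proportion_z(100, 100, 0, 100)
  expect_lt(r2$p, 1e-10)
  # cross-check against the chi-squared equivalence z^2 == X^2
  ct <- suppressWarnings(stats::chisq.test(
    rbind(c(492, 738), c(306, 522)), correct = FALSE))
  expect_equal(r1$z^2, unname(ct$statistic), tolerance = 1e-9)
  expect_error(two_proportion_z(5, 0, 1, 10), "n1 > 0")
})

test_that("pairwise chi-squared tests compare all group pairs", {
  same <- pairwise_chi_squared(list(a = c(5, 10), b = c(10, 20)))
  expect_equal(same$p, 1)
  # per-indication accuracies from the published testing cohort
  ind <- pairwise_chi_squared(list(cad = c(62, 68), pvi = c(46, 49),
                                   tavr = c(11, 11), lvad = c(10, 10)))
  expect_equal(nrow(ind), 6L)
  expect_true(all(ind$p > 0.05))
  ext <- pairwise_chi_squared(list(c(50, 50), c(0, 50)))
  expect_lt(ext$p, 1e-6)
  expect_error(pairwise_chi_squared(list(c(5, 10))), "at least 2")
  expect_error(pairwise_chi_squared(list(c(5, 10), c(0, 0))), "n = 0")
})
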