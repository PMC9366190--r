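#' Confusion matrix for binary WMA classification
#'
#' Positive class is `abnormal`; rows are the prediction, columns the ground
#' truth.
#'
#' @param pred,truth equal-length binary vectors: logical (TRUE = abnormal)
#'   or `"abnormal"`/`"normal"`.
#' @return object of class `wma_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 1L) stop("empty input")
  p <- .as_abnormal(pred)
  t <- .as_abnormal(truth)
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   fn = sum(!p & t), tn = sum(!p & !t))
}

.as_abnormal <- function(x) {
  if (is.logical(x)) return(x)
  lab <- as.character(x)
  if (!all(lab %in% c("abnormal", "normal")))
    stop("labels must be abnormal/normal or logical")
  lab == "abnormal"
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn nonnegative counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty confusion matrix")
  structure(as.list(counts), class = "wma_confusion")
}

#' @export
print.wma_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("abnormal", "normal"),
                              truth = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' Undefined rates (empty margin) are returned as NA and flagged, never
#' coerced to 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `sensitivity`, `specificity`, `accuracy` and
#'   `undefined` (character vector naming any undefined rate).
#' @export
sens_spec_acc <- function(cm) {
  stopifnot(inherits(cm, "wma_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  undef <- character()
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       accuracy = (cm$tp + cm$tn) / n, undefined = undef)
}

#' Cohen's kappa with 95\% confidence interval
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with the
#' asymptotic standard error \eqn{\sqrt{p_o (1 - p_o) / (N (1 - p_e)^2)}};
#' the interval is \eqn{\kappa \pm 1.96\, SE}.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `kappa`, `ci` (length-2 vector), `se`, `po`, `pe`.
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "wma_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
         (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (1 - pe < 1e-12) stop("degenerate marginals: chance agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa, ci = c(kappa - 1.96 * se, kappa + 1.96 * se),
       se = se, po = po, pe = pe)
}

#' Full agreement report for one cohort or stratum
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `agreement_report`: the counts plus sensitivity,
#'   specificity, accuracy, kappa and its 95\% CI.
#' @export
agreement_report <- function(cm) {
  s <- sens_spec_acc(cm)
  k <- tryCatch(cohens_kappa(cm), error = function(e) list(kappa = NA_real_,
                                                           ci = c(NA, NA)))
  structure(list(cm = cm, sensitivity = s$sensitivity,
                 specificity = s$specificity, accuracy = s$accuracy,
                 undefined = s$undefined,
                 kappa = k$kappa, kappa_ci = k$ci),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("sens %.3f  spec %.3f  acc %.3f  kappa %.3f [%.2f, %.2f]\n",
              x$sensitivity, x$specificity, x$accuracy, x$kappa,
              x$kappa_ci[1], x$kappa_ci[2]))
  invisible(x)
}

#' Re-bin per-video results into the six regional LV views
#'
#' @param pred,truth per-video binary results.
#' @param view per-video view index (0..5, as in [view_table()]).
#' @return named list of 6 [agreement_report()] objects (NULL with a flag
#'   for views without results); attribute `empty_views` lists them.
#' @export
rebin_by_view <- function(pred, truth, view) {
  if (anyNA(view)) stop("missing view tags")
  stopifnot(length(pred) == length(truth), length(pred) == length(view))
  vt <- view_table()
  out <- stats::setNames(vector("list", 6L), vt$wall)
  empty <- character()
  for (i in seq_len(6L)) {
    sel <- view == vt$n[i]
    if (!any(sel)) {
      empty <- c(empty, vt$wall[i])
      next
    }
    out[[i]] <- agreement_report(confusion_matrix(pred[sel], truth[sel]))
  }
  attr(out, "empty_views") <- empty
  out
}

#' Stratify per-study results by LVEF
#'
#' Bins: LVEF < 0.40, 0.40 to 0.60 (both boundaries assigned to the middle
#' bin), and > 0.60.
#'
#' @param pred,truth per-study binary results.
#' @param lvef per-study LVEF fraction in \[0, 1\].
#' @return named list of 3 [agreement_report()] objects (NULL for empty
#'   strata).
#' @export
stratify_by_lvef <- function(pred, truth, lvef) {
  if (any(lvef < 0 | lvef > 1, na.rm = TRUE))
    stop("lvef must lie within [0, 1]")
  bins <- cut(lvef, c(-Inf, 0.40, 0.60, Inf), right = TRUE,
              labels = c("lvef_lt_40", "lvef_40_60", "lvef_gt_60"))
  # cut() with right=TRUE puts 0.40 in the low bin; move it to the middle
  bins[lvef == 0.40] <- "lvef_40_60"
  out <- stats::setNames(vector("list", 3L), levels(bins))
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (any(sel))
      out[[b]] <- agreement_report(confusion_matrix(pred[sel], truth[sel]))
  }
  out
}

#' Two-tailed two-proportion z-test
#'
#' Pooled-variance z statistic for comparing proportions x1/n1 and x2/n2
#' between two independent cohorts, with a two-tailed normal p-value.
#'
#' @param x1,n1,x2,n2 successes and sizes of the two groups.
#' @return list with `z`, `p` and the two proportions.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Pairwise chi-squared tests between group proportions
#'
#' One 2 x 2 chi-squared test (without continuity correction, configurable)
#' per unordered pair of groups; no multiplicity correction is applied.
#' Degenerate pairs with identical proportions return p = 1.
#'
#' @param counts list of `c(successes, n)` pairs, optionally named.
#' @param correct apply Yates continuity correction.
#' @return data.frame with columns `group1`, `group2`, `statistic`, `p`.
#' @export
pairwise_chi_squared <- function(counts, correct = FALSE) {
  if (length(counts) < 2L) stop("need at least 2 groups")
  nm <- names(counts)
  if (is.null(nm)) nm <- paste0("group", seq_along(counts))
  for (g in counts) {
    stopifnot(length(g) == 2L)
    if (g[2] <= 0) stop("group with n = 0")
    if (g[1] < 0 || g[1] > g[2]) stop("successes outside [0, n]")
  }
  pairs <- utils::combn(seq_along(counts), 2)
  res <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- counts[[pairs[1, k]]]
    b <- counts[[pairs[2, k]]]
    if (a[1] / a[2] == b[1] / b[2]) {
      res$statistic[k] <- 0
      res$p[k] <- 1
      next
    }
    tab <- rbind(c(a[1], a[2] - a[1]), c(b[1], b[2] - b[1]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res$statistic[k] <- unname(ct$statistic)
    res$p[k] <- ct$p.value
  }
  res
}

#' Reference confusion matrices from the clinical validation cohort
#'
#' Published per-video and per-study confusion-matrix counts of the clinical
#' 343-study cohort (cross-validation and testing, the intermediate-LVEF
#' stratum, and the two expert-reader comparisons), bundled so the package's
#' agreement arithmetic can recompute every derived statistic from the raw
#' counts.
#'
#' @return data.frame with columns `cohort`, `level`, `stratum`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
clinical_reference_counts <- function() {
  path <- system.file("extdata", "clinical_cohort_counts.csv",
                      package = "vrwma", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
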