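#' Study-level split plan
#'
#' Studies (all six videos of a study travel together) are split 60/40 into
#' a cross-validation pool and a held-out test set; the pool is divided into
#' five equal-as-possible folds.
#'
#' @param train_val_fraction,test_fraction split fractions (must sum to 1).
#' @param n_folds cross-validation folds over the 60\% pool.
#' @param seed split seed.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(train_val_fraction = 0.6, test_fraction = 0.4,
                       n_folds = 5L, seed = 1L) {
  stopifnot(abs(train_val_fraction + test_fraction - 1) < 1e-9,
            n_folds >= 2L)
  structure(list(train_val_fraction = train_val_fraction,
                 test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Seeded study-level train/test split with CV folds
#'
#' The test set holds `round(test_fraction * N)` studies; the remainder forms
#' the cross-validation pool, dealt into `n_folds` folds of equal-as-possible
#' size.  No study appears in more than one partition.
#'
#' @param study_ids vector of unique study identifiers (>= 10).
#' @param plan a [split_plan()].
#' @return list with `test` (ids), `folds` (list of id vectors over the
#'   pool), `train_val` (pool ids) and per-fold `fold_sizes`.
#' @export
make_splits <- function(study_ids, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  if (anyDuplicated(study_ids)) stop("study_ids must be unique")
  n <- length(study_ids)
  if (n < 10L) stop("need at least 10 studies to split")
  withr::with_seed(plan$seed, {
    n_test <- round(plan$test_fraction * n)
    test <- sample(study_ids, n_test)
    pool <- setdiff(study_ids, test)
    folds <- cv_folds(pool, plan$n_folds, shuffle = TRUE)
  })
  sizes <- data.frame(fold = seq_along(folds),
                      n_val = lengths(folds),
                      n_train = length(pool) - lengths(folds))
  list(test = test, train_val = pool, folds = folds, fold_sizes = sizes)
}

#' Deal ids into k equal-as-possible folds
#'
#' @param ids id vector.
#' @param k fold count.
#' @param shuffle permute before dealing (uses the current RNG state).
#' @return list of k id vectors partitioning `ids`.
#' @export
cv_folds <- function(ids, k = 5L, shuffle = FALSE) {
  if (shuffle) ids <- sample(ids)
  split(ids, rep_len(seq_len(k), length(ids)))
}
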