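#' Training configuration for the sequence classifier
#'
#' The classifier is an LSTM over the four per-frame feature vectors (2048
#' recurrent units, tanh activation, sigmoid recurrent gate activations)
#' followed by a fully connected softmax head over the two classes
#' (abnormal, normal), trained end-to-end with categorical cross-entropy.
#'
#' @param units LSTM hidden units.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation loss, epochs.
#' @param val_fraction fraction of training videos held out for early
#'   stopping when no explicit validation set is given.
#' @param class_weight `"balanced"` weights the cross-entropy of each class
#'   inversely to its training frequency (abnormal videos are the minority
#'   in realistic cohorts); `"none"` leaves classes unweighted.
#' @param seed seed for weight initialisation and shuffling.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(units = 2048L, lr = 1e-4, batch_size = 16L,
                              max_epochs = 200L, patience = 20L,
                              val_fraction = 0.2,
                              class_weight = c("balanced", "none"),
                              seed = 1L) {
  structure(list(units = as.integer(units), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 class_weight = match.arg(class_weight),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

.class_levels <- c("abnormal", "normal")

.as_class_index <- function(labels) {
  # 0-based class index: abnormal = 0, normal = 1
  if (is.logical(labels)) return(ifelse(labels, 0L, 1L))
  lab <- as.character(labels)
  if (!all(lab %in% .class_levels)) stop("labels must be abnormal/normal")
  ifelse(lab == "abnormal", 0L, 1L)
}

.stack_features <- function(matrices) {
  n <- length(matrices)
  X <- array(0, c(n, 4L, 2048L))
  for (i in seq_len(n)) X[i, , ] <- unclass(matrices[[i]])
  X
}

#' Train the WMA sequence classifier
#'
#' Features are standardised per dimension (statistics from the training
#' videos only), then the LSTM + fully connected head is fit with Adam and
#' categorical cross-entropy, early-stopping on validation loss and keeping
#' the best-validation weights.  Training is deterministic for a given
#' configuration seed.
#'
#' @param matrices list of `feature_matrix` objects (4 x 2048).
#' @param labels per-video labels: logical (TRUE = abnormal) or
#'   `"abnormal"`/`"normal"`.
#' @param config a [classifier_config()].
#' @param val_matrices,val_labels optional explicit validation videos; when
#'   absent, `val_fraction` of the training videos is held out (seeded).
#' @param verbose print per-epoch losses.
#' @return object of class `wma_classifier`.
#' @export
train_classifier <- function(matrices, labels, config = classifier_config(),
                             val_matrices = NULL, val_labels = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  y <- .as_class_index(labels)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class")
  X <- .stack_features(matrices)
  if (is.null(val_matrices)) {
    n <- length(y)
    idx <- withr::with_seed(config$seed,
                            sample(n, max(2, round(config$val_fraction * n))))
    Xv <- X[idx, , , drop = FALSE]
    yv <- y[idx]
    X <- X[-idx, , , drop = FALSE]
    y <- y[-idx]
    if (length(unique(y)) < 2L)
      stop("training data contains a single class after validation split")
  } else {
    Xv <- .stack_features(val_matrices)
    yv <- .as_class_index(val_labels)
  }
  mu <- apply(X, 3, mean)
  sd <- pmax(apply(X, 3, stats::sd), 1e-8)
  X <- .standardize(X, mu, sd)
  Xv <- .standardize(Xv, mu, sd)
  cw <- c(1, 1)
  if (identical(config$class_weight, "balanced")) {
    n0 <- sum(y == 0L)
    n1 <- sum(y == 1L)
    cw <- length(y) / (2 * c(n0, n1))
  }
  fit <- cpp_lstm_train(X, y, Xv, yv, config$units, 2L, config$lr,
                        config$batch_size, config$max_epochs, config$patience,
                        config$seed, verbose, cw)
  structure(list(weights = fit$weights, mu = mu, sd = sd, config = config,
                 class_order = .class_levels,
                 history = list(train_loss = fit$train_loss,
                                val_loss = fit$val_loss,
                                best_epoch = fit$best_epoch,
                                best_val_loss = fit$best_val_loss)),
            class = "wma_classifier")
}

.standardize <- function(X, mu, sd) {
  d <- dim(X)
  Xm <- matrix(X, d[1] * d[2], d[3])
  Xm <- sweep(sweep(Xm, 2, mu, "-"), 2, sd, "/")
  array(Xm, d)
}

#' Predict WMA presence in one video
#'
#' @param model a trained [train_classifier()] result.
#' @param matrix a `feature_matrix` (4 x 2048).
#' @return list with `prob` (named probability pair summing to 1) and
#'   `label` (`"abnormal"`/`"normal"`; the 0.5 tie breaks to normal).
#' @export
predict_video <- function(model, matrix) {
  p <- predict_videos(model, list(matrix))
  list(prob = p$prob[1, ], label = p$label[1])
}

#' Predict WMA presence for a batch of videos
#'
#' @param model a trained classifier.
#' @param matrices list of `feature_matrix` objects.
#' @return list with `prob` (n x 2 matrix, columns abnormal/normal) and
#'   `label` (character vector).
#' @export
predict_videos <- function(model, matrices) {
  stopifnot(inherits(model, "wma_classifier"))
  X <- .standardize(.stack_features(matrices), model$mu, model$sd)
  prob <- cpp_lstm_predict(model$weights, X)
  colnames(prob) <- model$class_order
  label <- ifelse(prob[, "abnormal"] > 0.5, "abnormal", "normal")
  list(prob = prob, label = label)
}

#' Per-study prediction from six video predictions
#'
#' Applies the per-study rule to the six predicted video labels: abnormal
#' when at least `threshold` videos are predicted abnormal.
#'
#' @param model a trained classifier.
#' @param matrices list of exactly 6 `feature_matrix` objects, one per view.
#' @param threshold abnormal-video count threshold (default 2).
#' @return a `study_label`.
#' @export
predict_study <- function(model, matrices, threshold = 2L) {
  if (length(matrices) != 6L)
    stop("expected exactly 6 video feature matrices, got ", length(matrices))
  pred <- predict_videos(model, matrices)
  label_study(as.list(pred$label == "abnormal"), threshold = threshold)
}
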