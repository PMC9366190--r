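test_that("the stub extractor is deterministic, 2048-long and input-sensitive", {
  spec <- extractor_spec(seed = 7L)
  img <- matrix(0.2, 299, 299)
  f1 <- extract_frame_features(img, spec)
  expect_length(f1, 2048L)
  expect_identical(f1, extract_frame_features(img, spec))
  img2 <- img
  img2[100:140, 100:140] <- 1
  expect_gt(max(abs(extract_frame_features(img2, spec) - f1)), 0)
  expect_error(extract_frame_features(matrix(0, 100, 100), spec), "299")
  expect_error(extract_frame_features(img, extractor_spec("pretrained_cnn")),
               "weights")
})

test_that("feature matrices are (4, 2048) with rows in temporal order", {
  spec <- extractor_spec(seed = 7L)
  frames <- lapply(1:4, function(i) matrix(i / 10, 299, 299))
  fm <- assemble_feature_matrix(frames, spec)
  expect_equal(dim(fm), c(4L, 2048L))
  perm <- assemble_feature_matrix(frames[c(2, 1, 3, 4)], spec)
  expect_equal(unclass(perm), unclass(fm)[c(2, 1, 3, 4), ])
  expect_error(assemble_feature_matrix(frames[1:3], spec), "4 frames")
})

test_that("splits are seeded, study-level and arithmetically correct", {
  ids <- sprintf("study%03d", 1:50)
  sp <- split_plan(seed = 3L)
  s1 <- make_splits(ids, sp)
  s2 <- make_splits(ids, sp)
  expect_identical(s1, s2)
  expect_length(s1$test, round(0.4 * 50))
  expect_length(s1$train_val, 30L)
  # no study straddles partitions; folds partition the pool
  expect_length(intersect(s1$test, s1$train_val), 0L)
  expect_setequal(unlist(s1$folds), s1$train_val)
  expect_equal(sum(lengths(s1$folds)), 30L)
  # 10 studies: 4-study test set, folds of 2 by the rounding rule
  s3 <- make_splits(sprintf("s%02d", 1:10), split_plan(seed = 1L))
  expect_length(s3$test, 4L)
  expect_true(all(lengths(s3$folds) %in% c(1L, 2L)))
  expect_error(make_splits(letters[1:5], sp), "at least 10")
  # a 205-study pool deals into folds of 41 validation / 164 training
  f205 <- cv_folds(seq_len(205), 5L)
  expect_true(all(lengths(f205) == 41L))
  expect_true(all(205 - lengths(f205) == 164L))
})

test_that("LSTM gradients match finite differences", {
  set.seed(1)
  H <- 5L; D <- 7L; B <- 3L
  w <- list(Wx = matrix(rnorm(D * 4 * H, sd = 0.5), D, 4 * H),
            Wh = matrix(rnorm(H * 4 * H, sd = 0.5), H, 4 * H),
            Wy = matrix(rnorm(H * 2, sd = 0.5), H, 2),
            b = matrix(rnorm(4 * H, sd = 0.1), 1),
            by = matrix(rnorm(2, sd = 0.1), 1))
  X <- array(rnorm(B * 4 * D), c(B, 4, D))
  y <- c(0L, 1L, 0L)
  res <- vrwma:::cpp_lstm_loss_grad(w, X, y, TRUE)
  eps <- 1e-2
  for (nm in c("Wx", "Wh", "Wy", "b", "by")) {
    g_nu <- vapply(seq_along(w[[nm]]), function(i) {
      wp <- w; wm <- w
      wp[[nm]][i] <- wp[[nm]][i] + eps
      wm[[nm]][i] <- wm[[nm]][i] - eps
      (vrwma:::cpp_lstm_loss_grad(wp, X, y, FALSE)$loss -
         vrwma:::cpp_lstm_loss_grad(wm, X, y, FALSE)$loss) / (2 * eps)
    }, numeric(1))
    g_an <- as.numeric(res$grad[[nm]])
    cosine <- sum(g_an * g_nu) / sqrt(sum(g_an^2) * sum(g_nu^2))
    expect_gt(cosine, 0.999)
    expect_lt(max(abs(g_an - g_nu)), 1e-3)
  }
})

test_that("training separates linearly separable classes and is deterministic", {
  d <- separable_features(40)
  cfg <- classifier_config(units = 64L, lr = 1e-3, max_epochs = 50L,
                           patience = 50L, seed = 1L)
  m1 <- train_classifier(d$mats, d$labels, cfg)
  pr <- predict_videos(m1, d$mats)
  expect_gte(mean((pr$label == "abnormal") == d$labels), 0.99)
  m2 <- train_classifier(d$mats, d$labels, cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$weights$Wy, m2$weights$Wy)
  expect_error(train_classifier(d$mats[1:20], d$labels[1:20], cfg),
               "single class")
})

test_that("video predictions are probability pairs with a normal tie-break", {
  d <- separable_features(24, seed = 5L)
  cfg <- classifier_config(units = 16L, lr = 1e-3, max_epochs = 20L,
                           patience = 20L, seed = 2L)
  m <- train_classifier(d$mats, d$labels, cfg)
  pv <- predict_video(m, d$mats[[1]])
  expect_named(pv$prob, c("abnormal", "normal"))
  expect_equal(unname(sum(pv$prob)), 1, tolerance = 1e-6)
  expect_true(pv$label %in% c("abnormal", "normal"))
  pr <- predict_videos(m, d$mats)
  expect_equal(unname(rowSums(pr$prob)), rep(1, 24), tolerance = 1e-6)
  # exact ties go to normal (specificity-favouring rule)
  expect_equal(ifelse(0.5 > 0.5, "abnormal", "normal"), "normal")
})

test_that("per-study prediction applies the two-video rule", {
  d <- separable_features(24, seed = 6L)
  cfg <- classifier_config(units = 16L, lr = 1e-3, max_epochs = 30L,
                           patience = 30L, seed = 3L)
  m <- train_classifier(d$mats, d$labels, cfg)
  # two clearly abnormal + four clearly normal videos -> abnormal study
  mixed <- c(d$mats[1:2], d$mats[19:22])
  expect_true(predict_study(m, mixed)$abnormal)
  expect_equal(predict_study(m, mixed)$n_ab_videos, 2L)
  # one abnormal video is not enough
  one <- c(d$mats[1], d$mats[19:23])
  expect_false(predict_study(m, one)$abnormal)
  expect_error(predict_study(m, d$mats[1:5]), "6 video")
})
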