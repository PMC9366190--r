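#' Generate a cohort of phantom study specifications
#'
#' Half of the studies (by default) carry one wall-motion defect of the given
#' severity, 150 degrees wide in azimuth spanning most of the apex-to-base
#' extent (wide enough that the impaired surface exceeds the 35\% labeling
#' fraction in at least two of the six views); the rest contract normally.
#' Defect centres sit on the six AHA wall-centre azimuths (optionally
#' jittered), emulating infarcts centred on coronary territories; centring
#' keeps every view's impaired-surface fraction well away from the 35\%
#' labeling threshold, so the ground-truth view labels are unambiguous.  Study-to-study anatomical variability is
#' emulated by jittering the base radii (about 8\%) and the global
#' contraction (about 0.02 SD).
#'
#' @param n_studies cohort size.
#' @param abnormal_fraction fraction of studies given a defect.
#' @param severity defect severity (1 = akinetic, 0.5 = subtle).
#' @param seed cohort seed; every study gets a derived sub-seed.
#' @param grid_shape,voxel_size,n_frames phantom sampling parameters.
#' @param defect_width azimuthal defect width, degrees.
#' @param defect_extent apex-to-base fraction pair affected.
#' @param defect_jitter_deg uniform jitter around the wall-centre azimuth.
#' @return list of [phantom_spec()] objects; attribute `has_defect` flags the
#'   designed abnormal studies.
#' @export
make_phantom_cohort <- function(n_studies = 60L, abnormal_fraction = 0.5,
                                severity = 1, seed = 1L,
                                grid_shape = c(64L, 64L, 64L),
                                voxel_size = c(2, 2, 2), n_frames = 10L,
                                defect_width = 150,
                                defect_extent = c(0.1, 0.9),
                                defect_jitter_deg = 0) {
  n_ab <- round(abnormal_fraction * n_studies)
  has_defect <- rep(c(TRUE, FALSE), c(n_ab, n_studies - n_ab))
  res <- withr::with_seed(seed, {
    has_defect <- sample(has_defect)
    specs <- lapply(seq_len(n_studies), function(i) {
      radii <- c(25, 45) * stats::runif(2, 0.92, 1.08)
      contraction <- min(max(stats::rnorm(1, 0.8, 0.02), 0.7), 0.9)
      defects <- if (has_defect[i]) {
        list(defect_spec(azimuth_center = sample(view_table()$cam_azimuth, 1) +
                           stats::runif(1, -defect_jitter_deg,
                                        defect_jitter_deg),
                         azimuth_width = defect_width,
                         long_axis_extent = defect_extent,
                         severity = severity))
      } else list()
      phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                   n_frames = n_frames, base_radii = radii,
                   global_contraction = contraction, defects = defects,
                   seed = as.integer((seed * 977 + i) %% 2147483647))
    })
    list(specs = specs, has_defect = has_defect)
  })
  specs <- res$specs
  attr(specs, "has_defect") <- res$has_defect
  specs
}

#' Render, label and featurise one phantom study
#'
#' Runs the rendering and ground-truth arms for all six views of one study:
#' study-specific window level, ED-frame rendering with endocardial
#' visibility, projection of the per-face RS_CT map, per-view and per-study
#' labels, and the (4, 2048) feature matrix from the four selected input
#' frames.
#'
#' @param study a [generate_study()] result.
#' @param extractor an [extractor_spec()].
#' @param npix rendered frame side length, pixels.
#' @param rsct_source `"truth"` uses the phantom's analytic per-face RS_CT;
#'   `"mesh"` recomputes it from the ED/ES meshes via
#'   [establish_correspondence()] and [compute_rsct()].
#' @param rsct_cut,frac_cut,study_cut labeling thresholds.
#' @return list with `features` (6 feature matrices), `video_labels`,
#'   `study_label`, `abnormal_fractions`, `window`, `lvef`.
#' @export
label_phantom_study <- function(study, extractor = extractor_spec(),
                                npix = 128L, rsct_source = c("truth", "mesh"),
                                rsct_cut = -0.20, frac_cut = 0.35,
                                study_cut = 2L) {
  stopifnot(inherits(study, "phantom_study"))
  rsct_source <- match.arg(rsct_source)
  spec <- study$spec
  ed <- study$ed_index
  es <- study$es_index
  win <- compute_window_level(study$volumes[[ed]], study$masks[[ed]],
                              spec$voxel_size)
  idxm <- which(study$masks[[ed]], arr.ind = TRUE)
  center <- (colMeans(idxm) - 1) * spec$voxel_size
  long_axis <- diff(range(idxm[, 3] - 1)) * spec$voxel_size[3]
  mesh_ed <- study$meshes[[ed]]
  rs <- if (rsct_source == "truth") {
    rsct_map(study$truth_rsct, mesh_ed)
  } else {
    corr <- establish_correspondence(mesh_ed, study$meshes[[es]])
    compute_rsct(mesh_ed, study$meshes[[es]], corr)
  }
  frame_idx <- round(seq(ed, es, length.out = 4))
  vt <- view_table()
  features <- vector("list", 6L)
  vlabels <- vector("list", 6L)
  fracs <- numeric(6L)
  for (v in seq_len(6L)) {
    view <- vt[v, ]
    ed_frame <- render_frame(study$volumes[[ed]], view, win, spec$voxel_size,
                             center = center, long_axis_mm = long_axis,
                             npix = npix, mesh = mesh_ed, frame_index = ed)
    pmap <- project_rsct_to_view(rs, ed_frame, rsct_cut = rsct_cut)
    vlabels[[v]] <- label_view(pmap, frac_cut = frac_cut)
    fracs[v] <- vlabels[[v]]$abnormal_fraction
    imgs <- lapply(frame_idx, function(i) {
      img <- if (i == ed) ed_frame$image else
        render_frame(study$volumes[[i]], view, win, spec$voxel_size,
                     center = center, long_axis_mm = long_axis,
                     npix = npix, frame_index = i)$image
      resample_image(img, 299L)
    })
    features[[v]] <- assemble_feature_matrix(imgs, extractor)
    # mirror-image anatomy carries the same label; used for augmentation
    attr(features[[v]], "flipped") <- assemble_feature_matrix(
      lapply(imgs, function(im) im[, ncol(im):1]), extractor)
  }
  slabel <- label_study(vlabels, threshold = study_cut, lvef = study$lvef,
                        ed_index = ed, es_index = es)
  list(features = features, video_labels = vlabels, study_label = slabel,
       abnormal_fractions = fracs, window = win, lvef = study$lvef)
}

#' Phantom-cohort recovery experiment
#'
#' The package's core end-to-end check: generate a seeded phantom cohort,
#' derive ground-truth labels through the rendering + RS_CT arm, split 60/40
#' at the study level, run 5-fold cross-validation on the 60\% pool (each
#' fold's model early-stops on its validation fold) and evaluate the
#' fold-averaged predictions on the held-out 40\%, per video and per study.
#'
#' @param n_studies cohort size (default 60).
#' @param severity defect severity of the abnormal half.
#' @param seed master seed for cohort, split and training.
#' @param config a [classifier_config()]; the default caps the experiment's
#'   training budget at 20 epochs (patience 4, learning rate 1e-3, batch
#'   64), which is ample for this cohort size.
#' @param npix rendered frame side length.
#' @param extractor frame feature extractor.
#' @param n_folds cross-validation folds whose models are averaged.
#' @param verbose print progress.
#' @return list with `video_accuracy`, `study_accuracy`, `video_report`,
#'   `study_report`, per-fold validation accuracy, per-study labels and the
#'   split.
#' @export
run_phantom_experiment <- function(n_studies = 60L, severity = 1, seed = 1L,
                                   config = NULL, npix = 128L,
                                   extractor = extractor_spec(seed = 7L),
                                   n_folds = 5L, verbose = FALSE) {
  if (is.null(config))
    config <- classifier_config(units = 2048L, lr = 1e-3, batch_size = 64L,
                                max_epochs = 20L, patience = 4L,
                                seed = as.integer(seed))
  specs <- make_phantom_cohort(n_studies = n_studies, severity = severity,
                               seed = seed)
  studies <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    st <- generate_study(specs[[i]])
    studies[[i]] <- label_phantom_study(st, extractor = extractor,
                                        npix = npix)
    if (verbose) message("labelled study ", i, "/", n_studies,
                         " (n_ab_videos = ",
                         studies[[i]]$study_label$n_ab_videos, ")")
  }
  split <- make_splits(seq_len(n_studies),
                       split_plan(n_folds = n_folds,
                                  seed = as.integer(seed)))
  collect <- function(ids) {
    mats <- do.call(c, lapply(studies[ids], `[[`, "features"))
    labs <- unlist(lapply(studies[ids], function(s)
      vapply(s$video_labels, `[[`, logical(1), "abnormal")))
    list(mats = mats, labs = labs,
         study = vapply(studies[ids], function(s) s$study_label$abnormal,
                        logical(1)))
  }
  te <- collect(split$test)
  flipped <- function(mats) lapply(mats, attr, "flipped")
  te_flip <- flipped(te$mats)
  # 5-fold CV on the 60% pool; fold models are averaged on the test set,
  # with mirror augmentation in training and flip-averaged prediction
  prob_sum <- NULL
  fold_val_acc <- numeric(length(split$folds))
  histories <- vector("list", length(split$folds))
  for (k in seq_along(split$folds)) {
    tr_ids <- setdiff(split$train_val, split$folds[[k]])
    tr <- collect(tr_ids)
    va <- collect(split$folds[[k]])
    cfg_k <- config
    cfg_k$seed <- as.integer((config$seed * 131 + k) %% 2147483647)
    model <- train_classifier(c(tr$mats, flipped(tr$mats)),
                              c(tr$labs, tr$labs), config = cfg_k,
                              val_matrices = va$mats, val_labels = va$labs,
                              verbose = verbose)
    histories[[k]] <- model$history
    pv <- predict_videos(model, va$mats)
    fold_val_acc[k] <- mean((pv$label == "abnormal") == va$labs)
    pt <- predict_videos(model, te$mats)
    ptf <- predict_videos(model, te_flip)
    prob_sum <- if (is.null(prob_sum)) pt$prob + ptf$prob else
      prob_sum + pt$prob + ptf$prob
    if (verbose) message(sprintf("fold %d: val acc %.3f (best epoch %d)",
                                 k, fold_val_acc[k],
                                 model$history$best_epoch))
  }
  prob <- prob_sum / (2 * length(split$folds))
  pred_ab <- prob[, "abnormal"] > 0.5
  video_cm <- confusion_matrix(pred_ab, te$labs)
  n_per <- 6L
  pred_study <- vapply(seq_along(split$test), function(i) {
    sum(pred_ab[(i - 1L) * n_per + seq_len(n_per)]) >= 2L
  }, logical(1))
  study_cm <- confusion_matrix(pred_study, te$study)
  list(video_accuracy = sens_spec_acc(video_cm)$accuracy,
       study_accuracy = sens_spec_acc(study_cm)$accuracy,
       video_report = agreement_report(video_cm),
       study_report = agreement_report(study_cm),
       split = split, fold_val_acc = fold_val_acc, histories = histories,
       test_prob = prob, test_truth = te$labs,
       truth_video_abnormal_fraction = mean(unlist(lapply(studies, function(s)
         vapply(s$video_labels, `[[`, logical(1), "abnormal")))),
       lvef = vapply(studies, `[[`, numeric(1), "lvef"),
       study_truth = vapply(studies, function(s) s$study_label$abnormal,
                            logical(1)))
}
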