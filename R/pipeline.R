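#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the phantom-to-report chain: cohort, rendering,
#' labeling thresholds, extractor and training settings, and the seeds that
#' make the run reproducible.
#'
#' @param out_dir run directory.
#' @param n_studies,severity,abnormal_fraction phantom cohort settings.
#' @param npix rendered frame side length, pixels.
#' @param rsct_cut RS_CT threshold (values >= this are impaired).
#' @param frac_cut strict abnormal-pixel fraction threshold per view.
#' @param study_cut abnormal-video count threshold per study.
#' @param units,lr,batch_size,max_epochs,patience training settings.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, n_studies = 20L, severity = 1,
                       abnormal_fraction = 0.5, npix = 128L,
                       rsct_cut = -0.20, frac_cut = 0.35, study_cut = 2L,
                       units = 2048L, lr = 1e-3, batch_size = 16L,
                       max_epochs = 40L, patience = 6L, seed = 1L) {
  stopifnot(rsct_cut > -1, rsct_cut < 1, frac_cut > 0, frac_cut < 1,
            study_cut >= 1, study_cut <= 6)
  structure(list(out_dir = out_dir, n_studies = as.integer(n_studies),
                 severity = severity, abnormal_fraction = abnormal_fraction,
                 npix = as.integer(npix), rsct_cut = rsct_cut,
                 frac_cut = frac_cut, study_cut = as.integer(study_cut),
                 units = as.integer(units), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys matching [run_config()] arguments.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

#' Run the full phantom-to-report pipeline
#'
#' Executes phantom generation, rendering, RS_CT labeling, feature
#' extraction, study-level splitting, training, prediction and evaluation,
#' writing per-stage outputs and a manifest (config, seeds, stage timings,
#' counts) into the run directory.  Stages that already produced their
#' output file are skipped when `resume = TRUE`.
#'
#' @param config a [run_config()].
#' @param resume reuse existing stage outputs in `out_dir`.
#' @param verbose log one line per stage.
#' @return the run directory, invisibly; the evaluation report is written to
#'   `report.json`.
#' @export
run_end_to_end <- function(config, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), started = format(Sys.time()),
                   stages = list())
  say <- function(...) if (verbose) message("[vrwma] ", ...)
  stage_file <- function(f) file.path(config$out_dir, f)

  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 2))
    res
  }

  labels_path <- stage_file("labels.json")
  features_path <- stage_file("features.rds")
  if (resume && file.exists(features_path) && file.exists(labels_path)) {
    say("resuming: labels + features found")
    studies <- readRDS(features_path)
  } else {
    specs <- make_phantom_cohort(n_studies = config$n_studies,
                                 abnormal_fraction = config$abnormal_fraction,
                                 severity = config$severity,
                                 seed = config$seed)
    extractor <- extractor_spec(seed = 7L)
    studies <- tick("phantom_render_label", {
      lapply(seq_along(specs), function(i) {
        st <- generate_study(specs[[i]])
        label_phantom_study(st, extractor = extractor, npix = config$npix,
                            rsct_cut = config$rsct_cut,
                            frac_cut = config$frac_cut,
                            study_cut = config$study_cut)
      })
    })
    saveRDS(studies, features_path)
    all_labels <- lapply(studies, function(s)
      list(n_ab_videos = s$study_label$n_ab_videos,
           abnormal = s$study_label$abnormal, lvef = s$lvef,
           fractions = s$abnormal_fractions))
    jsonlite::write_json(all_labels, labels_path, auto_unbox = TRUE,
                         digits = NA)
    say("labelled ", length(studies), " studies; abnormal: ",
        sum(vapply(studies, function(s) s$study_label$abnormal, logical(1))))
  }

  split <- make_splits(seq_len(config$n_studies),
                       split_plan(seed = config$seed))
  jsonlite::write_json(split[c("test", "train_val")], stage_file("split.json"),
                       auto_unbox = FALSE)
  say("split: ", length(split$train_val), " train/val, ",
      length(split$test), " test studies")

  cfg <- classifier_config(units = config$units, lr = config$lr,
                           batch_size = config$batch_size,
                           max_epochs = config$max_epochs,
                           patience = config$patience, seed = config$seed)
  collect <- function(ids) {
    list(mats = do.call(c, lapply(studies[ids], `[[`, "features")),
         labs = unlist(lapply(studies[ids], function(s)
           vapply(s$video_labels, `[[`, logical(1), "abnormal"))))
  }
  tr <- collect(split$train_val)
  model <- tick("train", train_classifier(tr$mats, tr$labs, config = cfg))
  saveRDS(model, stage_file("model.rds"))
  say("trained: best epoch ", model$history$best_epoch)

  te <- collect(split$test)
  pred <- predict_videos(model, te$mats)
  video_rep <- agreement_report(confusion_matrix(pred$label == "abnormal",
                                                 te$labs))
  study_pred <- vapply(split$test, function(id)
    predict_study(model, studies[[id]]$features,
                  threshold = config$study_cut)$abnormal, logical(1))
  study_truth <- vapply(studies[split$test], function(s)
    s$study_label$abnormal, logical(1))
  study_rep <- agreement_report(confusion_matrix(study_pred, study_truth))
  report <- list(
    per_video = list(sensitivity = video_rep$sensitivity,
                     specificity = video_rep$specificity,
                     accuracy = video_rep$accuracy, kappa = video_rep$kappa,
                     kappa_ci = video_rep$kappa_ci),
    per_study = list(sensitivity = study_rep$sensitivity,
                     specificity = study_rep$specificity,
                     accuracy = study_rep$accuracy, kappa = study_rep$kappa))
  jsonlite::write_json(report, stage_file("report.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$finished <- format(Sys.time())
  manifest$counts <- list(
    studies = config$n_studies, videos = 6L * config$n_studies,
    abnormal_videos = sum(c(tr$labs, te$labs)))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("report written to ", stage_file("report.json"))
  invisible(config$out_dir)
}

#' Label a segmented CT study through the mesh pipeline
#'
#' The real-data arm: per-frame blood-pool volumes give ED/ES and LVEF,
#' meshes extracted from the ED and ES masks give the RS_CT map via surface
#' correspondence, and the six rendered views give the per-view and
#' per-study labels.
#'
#' @param volumes list of 3D HU arrays (canonical orientation).
#' @param masks list of binary LV masks.
#' @param voxel_size mm per axis.
#' @param npix rendered frame side length.
#' @param rsct_cut,frac_cut,study_cut labeling thresholds.
#' @return list with `video_labels`, `study_label`, `rsct`, `ed_index`,
#'   `es_index`, `lvef`.
#' @export
label_ct_study <- function(volumes, masks, voxel_size, npix = 128L,
                           rsct_cut = -0.20, frac_cut = 0.35, study_cut = 2L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  vols_ml <- vapply(masks, function(m) sum(m) * prod(voxel_size) / 1000,
                    numeric(1))
  phases <- find_ed_es(vols_ml)
  ed <- phases$ed_index
  es <- phases$es_index
  lvef <- compute_lvef(vols_ml[ed], vols_ml[es])
  idxm <- which(masks[[ed]], arr.ind = TRUE)
  center <- (colMeans(idxm) - 1) * voxel_size
  long_axis <- diff(range(idxm[, 3] - 1)) * voxel_size[3]
  mesh_ed <- extract_endocardial_mesh(masks[[ed]], voxel_size)
  # one long axis for the whole cycle: the ED axis
  mesh_es <- extract_endocardial_mesh(masks[[es]], voxel_size,
                                      axis_xy = center[1:2])
  corr <- establish_correspondence(mesh_ed, mesh_es)
  rs <- compute_rsct(mesh_ed, mesh_es, corr)
  win <- compute_window_level(volumes[[ed]], masks[[ed]], voxel_size)
  vt <- view_table()
  vlabels <- vector("list", 6L)
  for (v in seq_len(6L)) {
    ed_frame <- render_frame(volumes[[ed]], vt[v, ], win, voxel_size,
                             center = center, long_axis_mm = long_axis,
                             npix = npix, mesh = mesh_ed, frame_index = ed)
    pmap <- project_rsct_to_view(rs, ed_frame, rsct_cut = rsct_cut)
    vlabels[[v]] <- label_view(pmap, frac_cut = frac_cut)
  }
  slabel <- label_study(vlabels, threshold = study_cut, lvef = lvef,
                        ed_index = ed, es_index = es)
  list(video_labels = vlabels, study_label = slabel, rsct = rs,
       ed_index = ed, es_index = es, lvef = lvef)
}
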