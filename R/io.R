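#' Write a phantom study to disk
#'
#' Volumes and masks go to 4D NIfTI files (voxel size in the header), meshes
#' to one ASCII PLY per frame (shared face list), the spec and truth labels
#' to JSON.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- study$spec$grid_shape
  nfr <- study$spec$n_frames
  vol4 <- RNifti::asNifti(array(unlist(study$volumes), c(dm, nfr)))
  msk4 <- RNifti::asNifti(array(as.integer(unlist(study$masks)),
                                c(dm, nfr)))
  RNifti::pixdim(vol4) <- c(study$spec$voxel_size, 1)
  RNifti::pixdim(msk4) <- c(study$spec$voxel_size, 1)
  RNifti::writeNifti(vol4, file.path(dir, "volumes.nii.gz"))
  RNifti::writeNifti(msk4, file.path(dir, "masks.nii.gz"))
  for (i in seq_len(nfr))
    write_ply(study$meshes[[i]], file.path(dir, sprintf("mesh_%03d.ply", i)))
  spec <- study$spec
  spec$defects <- lapply(spec$defects, unclass)
  jsonlite::write_json(list(spec = unclass(spec),
                            truth_rsct = study$truth_rsct,
                            ed_index = study$ed_index,
                            es_index = study$es_index,
                            volumes_ml = study$volumes_ml,
                            lvef = study$lvef),
                       file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read volumes and masks written by [write_phantom_study()]
#'
#' @param dir study directory.
#' @return list with `volumes`, `masks` (lists of 3D arrays), `voxel_size`,
#'   `meta` (the study JSON).
#' @export
read_phantom_study <- function(dir) {
  vol4 <- RNifti::readNifti(file.path(dir, "volumes.nii.gz"))
  msk4 <- RNifti::readNifti(file.path(dir, "masks.nii.gz"))
  vox <- RNifti::pixdim(vol4)[1:3]
  nfr <- dim(vol4)[4]
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  list(volumes = lapply(seq_len(nfr), function(i)
         array(vol4[, , , i], dim(vol4)[1:3])),
       masks = lapply(seq_len(nfr), function(i)
         array(msk4[, , , i] > 0.5, dim(msk4)[1:3])),
       voxel_size = vox, meta = meta)
}

#' Write per-view and per-study labels as JSON
#'
#' @param video_labels list of 6 `video_label` objects.
#' @param study_label a `study_label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_json <- function(video_labels, study_label, path) {
  vt <- view_table()
  views <- lapply(seq_len(6L), function(v)
    list(view = vt$n[v], wall = vt$wall[v],
         abnormal_fraction = video_labels[[v]]$abnormal_fraction,
         abnormal = video_labels[[v]]$abnormal))
  jsonlite::write_json(list(views = views,
                            study = list(
                              n_ab_videos = study_label$n_ab_videos,
                              abnormal = study_label$abnormal,
                              lvef = study_label$lvef,
                              ed = study_label$ed_index,
                              es = study_label$es_index)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmark coordinates from JSON
#'
#' Expects `{"apex": [x,y,z], "base_center": [...], "rv_insertion": [...]}`
#' in mm world coordinates.
#'
#' @param path JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(j$apex, j$base_center, j$rv_insertion)
}
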