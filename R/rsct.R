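#' Locate end-diastole and end-systole from the volume curve
#'
#' ED is the frame with the largest and ES the frame with the smallest
#' segmented blood-pool volume; ties break to the earliest frame.
#'
#' @param volumes_ml numeric vector of per-frame blood-pool volumes (mL),
#'   voxel count times voxel volume.
#' @return list with `ed_index` and `es_index` (1-based).
#' @export
find_ed_es <- function(volumes_ml) {
  if (length(volumes_ml) < 4L) stop("need at least 4 frames")
  if (diff(range(volumes_ml)) == 0)
    stop("constant volume curve: no identifiable systole")
  list(ed_index = which.max(volumes_ml), es_index = which.min(volumes_ml))
}

#' Left-ventricular ejection fraction
#'
#' @param edv,esv end-diastolic and end-systolic volumes, mL.
#' @return LVEF as a fraction, (EDV - ESV) / EDV.
#' @export
compute_lvef <- function(edv, esv) {
  if (edv <= 0) stop("EDV must be positive")
  if (esv > edv) stop("ESV exceeds EDV")
  (edv - esv) / edv
}

#' Face correspondence between the ED and ES meshes
#'
#' Meshes that share topology and UV parameterisation (every phantom mesh,
#' and any pair extracted by [extract_endocardial_mesh()] at the same grid
#' resolution) get the identity mapping.  Otherwise each ED face maps to the
#' ES face with the nearest centroid, made one-to-one by greedy assignment in
#' order of increasing distance.
#'
#' @param mesh_ed,mesh_es [endo_mesh()] objects.
#' @param max_unmatched error when more than this fraction of ED faces cannot
#'   be matched.
#' @return object of class `face_correspondence`: integer vector `mapping`
#'   (ES face index per ED face, NA when unmatched).
#' @export
establish_correspondence <- function(mesh_ed, mesh_es, max_unmatched = 0.2) {
  n_ed <- nrow(mesh_ed$faces)
  n_es <- nrow(mesh_es$faces)
  same_topology <- n_ed == n_es && identical(mesh_ed$faces, mesh_es$faces)
  if (same_topology) {
    mapping <- seq_len(n_ed)
  } else {
    ce <- face_centroids(mesh_ed)
    cs <- face_centroids(mesh_es)
    cell <- max(2 * sqrt(stats::median(mesh_es$face_areas)), 1)
    span <- max(apply(rbind(ce, cs), 2, function(v) diff(range(v))))
    mapping <- rep(NA_integer_, n_ed)
    taken <- logical(n_es)
    # greedy one-to-one by increasing distance; faces that lose their
    # nearest target retry against the remaining targets
    for (round in 1:6) {
      open <- which(is.na(mapping))
      free <- which(!taken)
      if (!length(open) || !length(free)) break
      near <- cpp_nearest_face(ce[open, , drop = FALSE],
                               cs[free, , drop = FALSE], cell, 0.25 * span)
      ok <- !is.na(near)
      if (!any(ok)) break
      d <- sqrt(rowSums((ce[open[ok], , drop = FALSE] -
                           cs[free[near[ok]], , drop = FALSE])^2))
      for (j in order(d)) {
        f <- open[ok][j]
        tgt <- free[near[ok][j]]
        if (!taken[tgt]) {
          mapping[f] <- tgt
          taken[tgt] <- TRUE
        }
      }
    }
    if (mean(is.na(mapping)) > max_unmatched)
      stop(sprintf("surface correspondence failed: %.0f%% of faces unmatched",
                   100 * mean(is.na(mapping))))
  }
  structure(list(mapping = mapping, identity = same_topology),
            class = "face_correspondence")
}

#' Regional shortening map from corresponding meshes
#'
#' Computes \eqn{RS_{CT} = Area_{ES}/Area_{ED} - 1} per ED face, and the
#' per-vertex value as the mean over the faces containing each vertex.
#'
#' @param mesh_ed,mesh_es [endo_mesh()] objects.
#' @param corr a [establish_correspondence()] result.
#' @return object of class `rsct_map` with `per_face`, `per_vertex` and the
#'   ED mesh.
#' @export
compute_rsct <- function(mesh_ed, mesh_es, corr) {
  stopifnot(inherits(corr, "face_correspondence"))
  if (length(corr$mapping) != nrow(mesh_ed$faces))
    stop("correspondence does not cover the ED mesh")
  if (any(mesh_ed$face_areas <= 0)) stop("zero-area ED face")
  per_face <- rep(NA_real_, nrow(mesh_ed$faces))
  ok <- !is.na(corr$mapping)
  per_face[ok] <- mesh_es$face_areas[corr$mapping[ok]] /
    mesh_ed$face_areas[ok] - 1
  rsct_map(per_face, mesh_ed)
}

#' Construct an RS_CT map from per-face values
#'
#' @param per_face RS_CT scalar per ED face (>= -1 where defined).
#' @param mesh_ed the ED [endo_mesh()].
#' @return object of class `rsct_map`.
#' @export
rsct_map <- function(per_face, mesh_ed) {
  stopifnot(length(per_face) == nrow(mesh_ed$faces))
  if (any(per_face < -1, na.rm = TRUE)) stop("RS_CT below -1")
  nv <- nrow(mesh_ed$vertices)
  sums <- numeric(nv)
  cnts <- numeric(nv)
  for (k in 1:3) {
    v <- mesh_ed$faces[, k]
    ok <- !is.na(per_face)
    sums <- sums + unname(tapply_sum(v[ok], per_face[ok], nv))
    cnts <- cnts + unname(tapply_sum(v[ok], rep(1, sum(ok)), nv))
  }
  per_vertex <- ifelse(cnts > 0, sums / cnts, NA_real_)
  structure(list(per_face = per_face, per_vertex = per_vertex,
                 mesh_ed = mesh_ed),
            class = "rsct_map")
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Project an RS_CT map into a rendered view
#'
#' For every pixel of the ED-frame rendering with a visible endocardial face,
#' marks the pixel abnormal when that face's RS_CT is at or above the
#' impaired-shortening threshold (>= -0.20, inclusive).  Pixels without
#' visibility are excluded.
#'
#' @param rsct an [rsct_map()].
#' @param frame the ED [render_frame()] with a visibility map over the same
#'   mesh.
#' @param rsct_cut threshold; values >= `rsct_cut` count as abnormal.
#' @return object of class `projected_rsct`: logical matrix `abnormal` (NA
#'   where nothing is visible) plus pixel counts.
#' @export
project_rsct_to_view <- function(rsct, frame, rsct_cut = -0.20) {
  stopifnot(inherits(rsct, "rsct_map"), inherits(frame, "rendered_frame"))
  vis <- frame$visibility
  ids <- vis[!is.na(vis)]
  if (length(ids) && max(ids) > length(rsct$per_face))
    stop("visibility references faces outside the RS_CT map")
  abn <- matrix(NA, nrow(vis), ncol(vis))
  abn[!is.na(vis)] <- rsct$per_face[ids] >= rsct_cut
  structure(list(abnormal = abn,
                 n_visible = sum(!is.na(vis)),
                 n_abnormal = sum(abn, na.rm = TRUE),
                 rsct_cut = rsct_cut),
            class = "projected_rsct")
}

#' Label one video from its projected RS_CT map
#'
#' A view is abnormal when strictly more than `frac_cut` (default 35\%) of
#' its visible endocardial pixels carry impaired shortening.
#'
#' @param pmap a [project_rsct_to_view()] result.
#' @param frac_cut strict fraction threshold.
#' @return object of class `video_label`: `abnormal` (logical) and
#'   `abnormal_fraction`.
#' @export
label_view <- function(pmap, frac_cut = 0.35) {
  stopifnot(inherits(pmap, "projected_rsct"))
  if (pmap$n_visible == 0L) stop("no visible endocardial pixels")
  frac <- pmap$n_abnormal / pmap$n_visible
  structure(list(abnormal = frac > frac_cut, abnormal_fraction = frac),
            class = "video_label")
}

#' Per-study label from the six video labels
#'
#' A study is abnormal when at least `threshold` of its six videos are
#' abnormal (default 2, i.e. "more than one").
#'
#' @param video_labels list of exactly 6 [label_view()] results (or logicals).
#' @param threshold minimum abnormal-video count.
#' @param lvef,ed_index,es_index optional study metadata carried along.
#' @return object of class `study_label` with `abnormal`, `n_ab_videos`,
#'   `lvef`, `ed_index`, `es_index`.
#' @export
label_study <- function(video_labels, threshold = 2L, lvef = NA_real_,
                        ed_index = NA_integer_, es_index = NA_integer_) {
  if (length(video_labels) != 6L)
    stop("expected exactly 6 video labels, got ", length(video_labels))
  ab <- vapply(video_labels, function(v)
    if (inherits(v, "video_label")) v$abnormal else isTRUE(v), logical(1))
  n_ab <- sum(ab)
  structure(list(abnormal = n_ab >= threshold, n_ab_videos = n_ab,
                 lvef = lvef, ed_index = ed_index, es_index = es_index,
                 threshold = as.integer(threshold)),
            class = "study_label")
}
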