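#' Intensity window for volume rendering
#'
#' The window width is fixed at 150 HU for every study; the level is
#' study-specific (see [compute_window_level()]).
#'
#' @param level window level WL, HU.
#' @return object of class `window_setting` with fields `level` and `width`.
#' @export
window_setting <- function(level) {
  stopifnot(is.finite(level))
  structure(list(level = level, width = 150), class = "window_setting")
}

#' Study-specific window level from a blood-pool ROI
#'
#' WL equals the mean voxel intensity within a small spherical ROI placed at
#' the centroid of the LV blood pool; WW is fixed at 150 HU.
#'
#' @param volume 3D HU array.
#' @param mask logical blood-pool mask of the same shape.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param roi_radius_mm ROI sphere radius, mm.
#' @return a [window_setting()].
#' @export
compute_window_level <- function(volume, mask, voxel_size, roi_radius_mm = 5) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (sum(mask) == 0L) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  ctr_vox <- colMeans(idx)
  ctr_in_pool <- isTRUE(mask[round(ctr_vox[1]), round(ctr_vox[2]),
                             round(ctr_vox[3])])
  if (!ctr_in_pool) {
    warning("mask centroid lies outside the blood pool; using mask-wide mean")
    return(window_setting(mean(volume[mask])))
  }
  dm <- dim(volume)
  rv <- ceiling(roi_radius_mm / voxel_size)
  xr <- max(1, round(ctr_vox[1]) - rv[1]):min(dm[1], round(ctr_vox[1]) + rv[1])
  yr <- max(1, round(ctr_vox[2]) - rv[2]):min(dm[2], round(ctr_vox[2]) + rv[2])
  zr <- max(1, round(ctr_vox[3]) - rv[3]):min(dm[3], round(ctr_vox[3]) + rv[3])
  sub <- volume[xr, yr, zr, drop = FALSE]
  gx <- (xr - ctr_vox[1]) * voxel_size[1]
  gy <- (yr - ctr_vox[2]) * voxel_size[2]
  gz <- (zr - ctr_vox[3]) * voxel_size[3]
  d2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  window_setting(mean(sub[d2 <= roi_radius_mm^2]))
}

# camera geometry for a view: perspective source on the foreground-wall
# azimuth at distance `dist_factor` times the long-axis length, looking at
# the LV centre, up = +z
.view_camera <- function(view, center, long_axis_mm, dist_factor = 3,
                         fill_fraction = 0.8) {
  az <- view$cam_azimuth * pi / 180
  dist <- dist_factor * long_axis_mm
  cam <- center + dist * c(cos(az), sin(az), 0)
  tanfov <- (0.5 * long_axis_mm / fill_fraction) / dist
  list(cam = cam, look = center, up = c(0, 0, 1), tanfov = tanfov)
}

#' Render one volume-rendered frame
#'
#' Perspective ray casting with front-to-back alpha compositing: opacity ramps
#' linearly from 0 at WL - WW/2 to 1 at WL + WW/2 and the emitted grayscale
#' equals the opacity.  When a mesh is supplied, the per-pixel visibility map
#' records the index of the mesh face nearest to the first point where the
#' accumulated opacity crosses 0.5.
#'
#' @param volume 3D HU array in the canonical LV frame.
#' @param view one row of [view_table()] (data.frame or list).
#' @param window a [window_setting()].
#' @param voxel_size mm per axis (length 1 or 3).
#' @param center LV centre, world mm; defaults to the grid centre.
#' @param long_axis_mm LV long-axis length, mm; defaults to the z extent of
#'   the grid.
#' @param npix image side length in pixels (square frame).
#' @param mesh optional [endo_mesh()] for the visibility map.
#' @param frame_index stored in the result.
#' @param ray_step_mm ray marching step; default half the smallest voxel.
#' @param max_face_dist_mm visibility is dropped for pixels whose opacity
#'   crossing lies farther than this from any face centroid (screens out the
#'   basal cap and apex, which are not part of the open endocardial mesh).
#' @return object of class `rendered_frame` with `image` (npix x npix in
#'   \[0,1\]), `visibility` (integer matrix of face indices, NA where no
#'   surface is seen) and `frame_index`.
#' @export
render_frame <- function(volume, view, window, voxel_size,
                         center = NULL, long_axis_mm = NULL, npix = 128L,
                         mesh = NULL, frame_index = NA_integer_,
                         ray_step_mm = NULL, max_face_dist_mm = 5) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(inherits(window, "window_setting"))
  dm <- dim(volume)
  if (is.null(center)) center <- (dm - 1) * voxel_size / 2
  if (is.null(long_axis_mm)) long_axis_mm <- (dm[3] - 1) * voxel_size[3]
  if (is.null(ray_step_mm)) ray_step_mm <- 0.5 * min(voxel_size)
  geo <- .view_camera(as.list(view), center, long_axis_mm)
  res <- cpp_raycast(as.numeric(volume), as.integer(dm), voxel_size,
                     geo$cam, geo$look, geo$up, geo$tanfov, as.integer(npix),
                     window$level, window$width, ray_step_mm,
                     window$level - window$width)
  vis <- matrix(NA_integer_, npix, npix)
  if (!is.null(mesh)) {
    cent <- face_centroids(mesh)
    cell <- max(2 * sqrt(stats::median(mesh$face_areas)), 1)
    ids <- cpp_nearest_face(res$hits, cent, cell, max_face_dist_mm)
    vis <- matrix(ids, npix, npix)
  }
  structure(list(image = res$image, visibility = vis,
                 hits = res$hits, frame_index = as.integer(frame_index),
                 view = as.list(view)),
            class = "rendered_frame")
}

#' Render a full-cycle volume-rendering video for one view
#'
#' @param volumes list of 3D HU arrays spanning one cardiac cycle (>= 4).
#' @param view one row of [view_table()].
#' @param window shared [window_setting()] for every frame.
#' @param voxel_size mm per axis.
#' @param meshes optional list of per-frame [endo_mesh()] objects for
#'   visibility maps.
#' @param ... passed to [render_frame()].
#' @return object of class `vr_video` with `view`, `frames` (list of
#'   `rendered_frame`) and `pixel_shape`.
#' @export
render_video <- function(volumes, view, window, voxel_size, meshes = NULL,
                         ...) {
  if (length(volumes) < 4L) stop("a VR video needs at least 4 frames")
  frames <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    frames[[i]] <- render_frame(volumes[[i]], view, window, voxel_size,
                                mesh = if (!is.null(meshes)) meshes[[i]],
                                frame_index = i, ...)
  }
  structure(list(view = as.list(view), frames = frames,
                 pixel_shape = dim(frames[[1]]$image)),
            class = "vr_video")
}

#' Select the four classifier input frames
#'
#' Picks ED, ES and two interior systolic frames evenly spaced between them
#' (`round(seq(ed, es, length.out = 4))`), and resamples each to
#' 299 x 299 pixels.  Frame indices are 1-based.
#'
#' @param video a [render_video()] result.
#' @param ed,es ED and ES frame indices (1-based, `ed != es`).
#' @param out_size output side length (299 matches the feature extractor).
#' @return list of 4 matrices (`out_size` x `out_size`), with attribute
#'   `frame_indices`.
#' @export
select_input_frames <- function(video, ed, es, out_size = 299L) {
  stopifnot(inherits(video, "vr_video"))
  nfr <- length(video$frames)
  if (ed == es) stop("ed and es must differ")
  if (ed < 1 || es < 1 || ed > nfr || es > nfr) stop("frame index out of range")
  if (abs(es - ed) < 3) {
    warning("fewer than 2 interior frames between ED and ES; duplicating ",
            "nearest frames")
  }
  idx <- round(seq(ed, es, length.out = 4))
  out <- lapply(idx, function(i)
    resample_image(video$frames[[i]]$image, out_size))
  attr(out, "frame_indices") <- idx
  out
}

#' Bilinear image resampling
#'
#' @param img numeric matrix.
#' @param out_size output side length (square output).
#' @return resampled matrix.
#' @export
resample_image <- function(img, out_size) {
  nr <- nrow(img); nc <- ncol(img)
  # map output pixel centres into input pixel-centre coordinates
  rx <- (seq_len(out_size) - 0.5) * nr / out_size + 0.5
  cx <- (seq_len(out_size) - 0.5) * nc / out_size + 0.5
  rx <- pmin(pmax(rx, 1), nr); cx <- pmin(pmax(cx, 1), nc)
  r0 <- pmin(floor(rx), nr - 1L); c0 <- pmin(floor(cx), nc - 1L)
  fr <- rx - r0; fc <- cx - c0
  a <- img[cbind(rep(r0, out_size), rep(c0, each = out_size))]
  b <- img[cbind(rep(r0 + 1, out_size), rep(c0, each = out_size))]
  d <- img[cbind(rep(r0, out_size), rep(c0 + 1, each = out_size))]
  e <- img[cbind(rep(r0 + 1, out_size), rep(c0 + 1, each = out_size))]
  w1 <- rep(1 - fr, out_size) * rep(1 - fc, each = out_size)
  w2 <- rep(fr, out_size) * rep(1 - fc, each = out_size)
  w3 <- rep(1 - fr, out_size) * rep(fc, each = out_size)
  w4 <- rep(fr, out_size) * rep(fc, each = out_size)
  matrix(a * w1 + b * w2 + d * w3 + e * w4, out_size, out_size)
}

#' Write a rendered video as a numbered PNG sequence
#'
#' Lossless canonical output format; one grayscale PNG per frame.
#'
#' @param video a [render_video()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
write_video_png <- function(video, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(video$frames))
  for (i in seq_along(video$frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
    png::writePNG(pmin(pmax(video$frames[[i]]$image, 0), 1), paths[i])
  }
  invisible(paths)
}
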