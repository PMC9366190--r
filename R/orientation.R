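#' LV orientation landmarks
#'
#' @param apex,base_center,rv_insertion mm triples in world coordinates
#'   (voxel index times voxel size, voxel centres, 0-based).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(apex, base_center, rv_insertion) {
  stopifnot(length(apex) == 3L, length(base_center) == 3L,
            length(rv_insertion) == 3L)
  if (sqrt(sum((apex - base_center)^2)) < 1e-6)
    stop("apex and base_center coincide")
  structure(list(apex = as.numeric(apex), base_center = as.numeric(base_center),
                 rv_insertion = as.numeric(rv_insertion)),
            class = "landmark_set")
}

#' The six regional projection views
#'
#' Fixed pairing of projection angle theta = 60 * n with the mid-cavity AHA
#' wall shown on the foreground.  Canonical frame convention: apex at low z,
#' base at high z, anterior wall centred on +y ("12 o'clock"); wall-centre
#' azimuths in math-convention degrees are anterior 90, anterolateral 30,
#' inferolateral -30, inferior -90, inferoseptal -150 (= 210), anteroseptal
#' 150.  The camera for view n sits on the azimuth of its foreground wall,
#' `cam_azimuth = 30 - 60 n`.
#'
#' @return data.frame with columns `n`, `theta`, `wall`, `cam_azimuth`.
#' @export
view_table <- function() {
  data.frame(
    n = 0:5,
    theta = 60 * (0:5),
    wall = c("anterolateral", "inferolateral", "inferior",
             "inferoseptal", "anteroseptal", "anterior"),
    cam_azimuth = (30 - 60 * (0:5)) %% 360,
    stringsAsFactors = FALSE
  )
}

#' Align a volume to the canonical LV frame
#'
#' Resamples the volume so that the apex-to-base direction becomes +z and the
#' anterior wall is centred on +y.  The septal direction is taken as the
#' component of (rv_insertion - long-axis midpoint) perpendicular to the long
#' axis and is mapped to azimuth 180 degrees (-x), which places the anterior
#' wall at 12 o'clock in x-y slices under the package's wall-azimuth
#' convention (see [view_table()]).  Trilinear interpolation; the output grid
#' has the same shape and voxel size as the input, with the LV centre (the
#' apex/base midpoint) mapped to the grid centre.
#'
#' @param volume 3D numeric array (HU).
#' @param landmarks a [landmark_set()].
#' @param voxel_size mm per axis (length 1 or 3).
#' @param fill HU value used outside the input grid.
#' @return 3D array of the same shape, aligned.
#' @export
align_long_axis <- function(volume, landmarks, voxel_size, fill = -1024) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  u <- landmarks$base_center - landmarks$apex
  u <- u / sqrt(sum(u^2))
  mid <- (landmarks$apex + landmarks$base_center) / 2
  s <- landmarks$rv_insertion - mid
  s <- s - sum(s * u) * u
  ns <- sqrt(sum(s^2))
  if (ns < 1e-6)
    stop("degenerate landmarks: rv_insertion collinear with the long axis")
  s <- s / ns
  ex <- -s
  ez <- u
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  B <- cbind(ex, ey, ez)  # columns: canonical axes in input world coords
  dm <- dim(volume)
  c_out <- (dm - 1) * voxel_size / 2
  # input voxel coords = (B (q - c_out) + mid) / vox, q = out voxel * vox
  A <- diag(1 / voxel_size) %*% B %*% diag(voxel_size)
  t0 <- (mid - as.vector(B %*% c_out)) / voxel_size
  out <- cpp_resample_affine(as.numeric(volume), as.integer(dm), A,
                             t0, as.integer(dm), fill)
  array(out, dm)
}

#' Rotate a volume about the canonical long axis
#'
#' Convenience resampler used for view-equivalence checks: rotating the
#' volume by `-60` degrees and rendering view `n` reproduces view `n + 1` of
#' the unrotated volume (the camera azimuth of view `n + 1` is 60 degrees
#' below that of view `n`).
#'
#' @param volume 3D array; @param angle_deg rotation in degrees;
#' @param voxel_size mm per axis; @param fill fill value outside the grid.
#' @return rotated 3D array of the same shape.
#' @export
rotate_volume_z <- function(volume, angle_deg, voxel_size, fill = -1024) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  dm <- dim(volume)
  ctr <- (dm - 1) * voxel_size / 2
  th <- angle_deg * pi / 180
  # content azimuth increases by -angle: sample input at azimuth +angle
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A <- diag(1 / voxel_size) %*% R %*% diag(voxel_size)
  t0 <- (ctr - as.vector(R %*% ctr)) / voxel_size
  array(cpp_resample_affine(as.numeric(volume), as.integer(dm), A, t0,
                            as.integer(dm), fill), dm)
}
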