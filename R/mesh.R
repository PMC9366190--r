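#' Endocardial triangle mesh
#'
#' Lightweight container for an endocardial surface: vertices in mm (world
#' coordinates), triangular faces as 1-based vertex index triples, per-face
#' areas in mm^2.  Phantom and mask-derived meshes share an azimuth-by-long-axis
#' UV parameterisation, stored in `uv`, which carries exact face
#' correspondence across frames.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param frame_index cardiac frame this mesh belongs to.
#' @param uv optional per-vertex parameter data.frame (`az` degrees, `v`
#'   apex-to-base fraction).
#' @return object of class `endo_mesh`.
#' @export
endo_mesh <- function(vertices, faces, frame_index = NA_integer_, uv = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    stop("faces reference invalid vertices")
  structure(list(vertices = vertices, faces = faces,
                 face_areas = .tri_areas(vertices, faces),
                 frame_index = as.integer(frame_index), uv = uv),
            class = "endo_mesh")
}

.tri_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.endo_mesh <- function(x, ...) {
  cat(sprintf("endocardial mesh: %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_areas)))
  invisible(x)
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Extract the endocardial surface mesh from a binary LV mask
#'
#' The mask is smoothed with a one-voxel Gaussian kernel and the 0.5
#' iso-level of the smoothed field is sampled on an azimuth-by-long-axis UV
#' grid by casting horizontal rays outward from the long axis (the in-plane
#' centroid line of the blood pool); valid for the star-shaped geometry of an
#' isolated LV blood pool.  The apex and base levels are located at sub-voxel
#' precision along the axis.  Along every azimuth the mesh rows sit at equal
#' fractions `(j + 0.5) / (n_long + 1)` of the meridian's arc length, so that
#' when the wall deforms by a per-meridian similarity (the dominant motion of
#' a contracting LV) rows on meshes from different frames correspond to the
#' same material points; meshes extracted at the same resolution share
#' topology and parameterisation.
#'
#' @param mask logical 3D array (single connected component).
#' @param voxel_size mm per axis (length 1 or 3).
#' @param n_az,n_long UV grid resolution.
#' @param sigma_vox Gaussian smoothing in voxel units.
#' @param axis_xy optional in-plane (x, y) world position of the long axis;
#'   defaults to the mask centroid.  Pass the ED value when extracting other
#'   frames of the same study so all meshes share one axis.
#' @return an [endo_mesh()].
#' @export
extract_endocardial_mesh <- function(mask, voxel_size, n_az = 96L,
                                     n_long = 48L, sigma_vox = 1,
                                     axis_xy = NULL) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  dm <- dim(mask)
  if (sum(mask) == 0L) stop("empty mask")
  lab <- cpp_label3d(as.logical(mask), as.integer(dm))
  ncomp <- max(lab)
  if (ncomp > 1L) {
    big <- sum(lab == 2L) > 0.1 * sum(lab == 1L)
    if (big) stop(sprintf("mask has %d large connected components; expected 1",
                          ncomp))
    mask <- array(lab == 1L, dm)  # discard speckle components
  }
  sm <- cpp_smooth3d(as.numeric(mask), as.integer(dm), sigma_vox)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- (colMeans(idx) - 1) * voxel_size  # world mm
  if (!is.null(axis_xy)) ctr[1:2] <- axis_xy
  # sub-voxel apex/base along the axis line
  zspan <- (dm[3] - 1) * voxel_size[3]
  down <- cpp_ray_isocrossing(sm, dm, voxel_size,
                              matrix(ctr, 1), matrix(c(0, 0, -1), 1),
                              0.5, zspan, 0.25 * min(voxel_size))
  up <- cpp_ray_isocrossing(sm, dm, voxel_size,
                            matrix(ctr, 1), matrix(c(0, 0, 1), 1),
                            0.5, zspan, 0.25 * min(voxel_size))
  if (is.na(down) || is.na(up))
    stop("mask centroid lies outside the smoothed blood pool")
  z_apex <- ctr[3] - down
  z_base <- ctr[3] + up
  # dense meridian profile per azimuth, then rows at equal arc fractions
  n_dense <- 4L * (n_long + 1L)
  zfr <- (seq_len(n_dense) - 0.5) / n_dense
  phi <- (seq_len(n_az) - 1L) * 360 / n_az
  dense <- expand.grid(az = phi, v = zfr)
  zz <- z_apex + dense$v * (z_base - z_apex)
  orig <- cbind(ctr[1], ctr[2], zz)
  dirs <- cbind(cos(dense$az * pi / 180), sin(dense$az * pi / 180), 0)
  rmax <- max(dm[1:2] * voxel_size[1:2])
  rad <- cpp_ray_isocrossing(sm, dm, voxel_size, orig, dirs, 0.5,
                             rmax, 0.25 * min(voxel_size))
  R <- matrix(rad, n_az, n_dense)  # azimuth x dense row
  if (anyNA(R)) {
    # isolated failures (e.g. rays grazing the apex) take the ring median
    for (j in seq_len(n_dense)) {
      med <- stats::median(R[, j], na.rm = TRUE)
      R[is.na(R[, j]), j] <- med
    }
    if (anyNA(R)) stop("could not locate the endocardial surface")
  }
  Z <- matrix(zz, n_az, n_dense)
  vfr <- (seq_len(n_long + 1L) - 0.5) / (n_long + 1L)
  verts <- matrix(0, n_az * (n_long + 1L), 3L)
  for (i in seq_len(n_az)) {
    seg <- sqrt(diff(R[i, ])^2 + diff(Z[i, ])^2)
    arc <- c(0, cumsum(seg))
    tgt <- vfr * arc[n_dense]
    rr <- stats::approx(arc, R[i, ], xout = tgt)$y
    zr <- stats::approx(arc, Z[i, ], xout = tgt)$y
    rows <- i + (seq_len(n_long + 1L) - 1L) * n_az
    verts[rows, ] <- cbind(ctr[1] + rr * dirs[i, 1],
                           ctr[2] + rr * dirs[i, 2], zr)
  }
  uv <- expand.grid(az = phi, v = vfr)
  fc <- .uv_grid_faces(n_az, n_long)
  endo_mesh(verts, fc, uv = uv)
}

.uv_grid_faces <- function(n_az, n_long) {
  fi <- vector("list", n_long)
  for (j in seq_len(n_long)) {
    base0 <- (j - 1L) * n_az
    i <- seq_len(n_az)
    inext <- c(seq_len(n_az - 1L) + 1L, 1L)
    v00 <- base0 + i; v10 <- base0 + inext
    v01 <- base0 + n_az + i; v11 <- base0 + n_az + inext
    fi[[j]] <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  }
  do.call(rbind, fi)
}

#' Write / read a mesh as ASCII PLY
#'
#' Minimal PLY writer and reader for the package's triangle meshes.
#'
#' @param mesh an [endo_mesh()].
#' @param path file path.
#' @return `read_ply` returns an [endo_mesh()]; `write_ply` its path,
#'   invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hend <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  verts <- matrix(scan(text = lines[hend + seq_len(nv)], quiet = TRUE),
                  nv, 3, byrow = TRUE)
  fc <- matrix(scan(text = lines[hend + nv + seq_len(nf)], quiet = TRUE),
               nf, 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  endo_mesh(verts, fc)
}
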