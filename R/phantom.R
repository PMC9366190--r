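#' Specify a synthetic 4DCT LV blood-pool phantom
#'
#' Defines a seeded, fully analytic stand-in for a contrast-enhanced cardiac
#' 4DCT study of an isolated left-ventricular blood pool.  The endocardial
#' surface is a truncated ellipsoid whose wall moves between end-diastole (ED)
#' and end-systole (ES) by a direction-dependent similarity scaling about the
#' ellipsoid centre, so that local endocardial patch areas scale exactly by the
#' square of the local scale factor.  Regional wall-motion defects are angular
#' sectors in which the ED-to-ES scale factor is raised toward 1 (severity 1 =
#' fully akinetic).
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param n_frames frames per cardiac cycle (>= 4).  Frame 1 is ED by
#'   construction; ES falls at the frame nearest 40\% of the cycle.
#' @param base_radii mm pair: endocardial short-axis radius and long-axis
#'   semi-length at ED.
#' @param global_contraction ED-to-ES short-axis radius ratio of the normal
#'   wall, in (0, 1).
#' @param blood_hu,background_hu Hounsfield units of the blood pool and of
#'   everything outside it.
#' @param noise_sd HU standard deviation of Gaussian noise added inside the
#'   blood pool only (the inputs emulated here are already blood-pool
#'   isolated, so the background stays exactly `background_hu`).
#' @param defects list of [defect_spec()] objects.
#' @param seed integer seed; two calls with the same spec give bit-identical
#'   studies.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(2, 2, 2),
                         n_frames = 10L,
                         base_radii = c(25, 45),
                         global_contraction = 0.8,
                         blood_hu = 520,
                         background_hu = 0,
                         noise_sd = 30,
                         defects = list(),
                         seed = 1L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            all(grid_shape >= 2), all(voxel_size > 0))
  if (n_frames < 4L) stop("n_frames must be >= 4")
  if (!(global_contraction > 0 && global_contraction < 1))
    stop("global_contraction must be in (0, 1)")
  if (any(base_radii <= 0)) stop("base_radii must be positive")
  if (blood_hu - background_hu <= 150)
    stop("blood_hu - background_hu must exceed 150 HU for renderable contrast")
  for (d in defects) stopifnot(inherits(d, "defect_spec"))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 n_frames = as.integer(n_frames),
                 base_radii = as.numeric(base_radii),
                 global_contraction = global_contraction,
                 blood_hu = blood_hu, background_hu = background_hu,
                 noise_sd = noise_sd, defects = defects,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify a regional wall-motion defect
#'
#' @param azimuth_center degrees about the long axis (math convention; the
#'   anterior wall centre is at 90).
#' @param azimuth_width degrees, in (0, 360].
#' @param long_axis_extent ordered fraction pair within \[0, 1\], the
#'   apex-to-base span affected (0 = apex, 1 = base).
#' @param severity fraction in \[0, 1\]; 0 leaves contraction normal, 1 makes
#'   the sector akinetic.
#' @return an object of class `defect_spec`.
#' @export
defect_spec <- function(azimuth_center, azimuth_width = 120,
                        long_axis_extent = c(0.2, 0.8), severity = 1) {
  if (!(azimuth_width > 0 && azimuth_width <= 360))
    stop("azimuth_width must be in (0, 360]")
  if (length(long_axis_extent) != 2L ||
      long_axis_extent[1] > long_axis_extent[2] ||
      long_axis_extent[1] < 0 || long_axis_extent[2] > 1)
    stop("long_axis_extent must be an ordered pair within [0, 1]")
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  structure(list(azimuth_center = azimuth_center,
                 azimuth_width = azimuth_width,
                 long_axis_extent = long_axis_extent,
                 severity = severity),
            class = "defect_spec")
}

# fraction of the long-axis semi-length kept above the equator; the basal cap
# is the flat truncation plane
.trunc_frac <- 0.5
# raised-cosine transition width at defect sector edges, degrees / long fraction
.az_soft_deg <- 10
.long_soft <- 0.05

# smooth 0..1 window over azimuth (degrees, wrap-aware) for one defect
.defect_weight <- function(defect, azimuth, long_pos) {
  half <- defect$azimuth_width / 2
  soft <- min(.az_soft_deg, half)
  d <- abs(((azimuth - defect$azimuth_center + 180) %% 360) - 180)
  w_az <- ifelse(d <= half - soft, 1,
                 ifelse(d >= half, 0, 0.5 * (1 + cos(pi * (d - (half - soft)) / soft))))
  ext <- defect$long_axis_extent
  softl <- min(.long_soft, (ext[2] - ext[1]) / 2)
  dl_lo <- long_pos - ext[1]
  dl_hi <- ext[2] - long_pos
  w_lo <- ifelse(dl_lo >= softl, 1, ifelse(dl_lo <= 0, 0,
                 0.5 * (1 - cos(pi * dl_lo / softl))))
  w_hi <- ifelse(dl_hi >= softl, 1, ifelse(dl_hi <= 0, 0,
                 0.5 * (1 - cos(pi * dl_hi / softl))))
  w_az * pmin(w_lo, w_hi)
}

# local ED->ES scale factor at a surface location (vectorised)
.es_scale <- function(spec, azimuth, long_pos) {
  g <- spec$global_contraction
  w <- numeric(max(length(azimuth), length(long_pos)))
  for (d in spec$defects)
    w <- pmax(w, d$severity * .defect_weight(d, azimuth, long_pos))
  g + (1 - g) * w
}

#' Closed-form regional shortening at a surface location
#'
#' Analytic oracle for the regional shortening value
#' \eqn{RS_{CT} = Area_{ES}/Area_{ED} - 1}: under the phantom's similarity
#' deformation a local surface patch at (azimuth, long_pos) scales by the local
#' factor `s` in both tangent directions, so its area ratio is exactly
#' \eqn{s^2}.
#'
#' @param spec a [phantom_spec()].
#' @param azimuth degrees about the long axis.
#' @param long_pos apex-to-base fraction in \[0, 1\].
#' @return RS_CT scalar (vectorised over `azimuth` / `long_pos`).
#' @export
analytic_rsct <- function(spec, azimuth, long_pos) {
  stopifnot(inherits(spec, "phantom_spec"))
  .es_scale(spec, azimuth, long_pos)^2 - 1
}

# cosine-eased systolic fraction: 0 at ED (frame 1), 1 at ES, back toward 0
# over diastole; unique extrema at ED and ES
.cycle_beta <- function(n_frames, es_index) {
  t <- seq_len(n_frames) - 1L
  es <- es_index - 1L
  beta <- numeric(n_frames)
  sys <- t <= es
  beta[sys] <- 0.5 * (1 - cos(pi * t[sys] / es))
  beta[!sys] <- 0.5 * (1 - cos(pi * (n_frames - t[!sys]) / (n_frames - es)))
  beta
}

# geometry shared by volume voxelisation and mesh construction
.phantom_geom <- function(spec) {
  ctr <- (spec$grid_shape - 1) * spec$voxel_size / 2
  a <- spec$base_radii[1]
  b <- spec$base_radii[2]
  z_apex <- ctr[3] - b
  z_base <- ctr[3] + .trunc_frac * b
  list(ctr = ctr, a = a, b = b, z_apex = z_apex, z_base = z_base)
}

#' Generate a synthetic 4DCT LV blood-pool study
#'
#' Voxelises the deforming truncated ellipsoid into HU volumes and binary
#' masks for every cardiac frame, builds an endocardial surface mesh on a
#' fixed azimuth-by-long-axis UV grid at ED and deforms it per frame (exact
#' face-index correspondence across frames), and evaluates the analytic
#' per-face ground-truth regional shortening.
#'
#' @param spec a [phantom_spec()].
#' @param n_az,n_long mesh resolution: azimuthal steps and long-axis rings.
#' @return an object of class `phantom_study` with elements `volumes`,
#'   `masks`, `meshes`, `truth_rsct`, `ed_index`, `es_index`, `volumes_ml`,
#'   `lvef` and the originating `spec`.
#' @export
generate_study <- function(spec, n_az = 96L, n_long = 48L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_geom(spec)
  if (2 * g$a / max(spec$voxel_size) < 8)
    stop("grid too coarse: fewer than 8 voxels across the short axis")
  es_index <- round(0.4 * spec$n_frames) + 1L
  beta <- .cycle_beta(spec$n_frames, es_index)

  dm <- spec$grid_shape
  ix <- (seq_len(dm[1]) - 1) * spec$voxel_size[1] - g$ctr[1]
  iy <- (seq_len(dm[2]) - 1) * spec$voxel_size[2] - g$ctr[2]
  iz <- (seq_len(dm[3]) - 1) * spec$voxel_size[3] - g$ctr[3]
  X <- array(rep(ix, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(iy, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(iz, each = dm[1] * dm[2]), dm)
  r <- sqrt(X^2 + Y^2 + Z^2)
  nz <- r > 0
  dx <- X / pmax(r, 1e-9); dy <- Y / pmax(r, 1e-9); dz <- Z / pmax(r, 1e-9)
  # ED radius along each direction: ellipsoid wall or basal truncation plane
  t_ell <- 1 / sqrt((dx^2 + dy^2) / g$a^2 + dz^2 / g$b^2)
  zb <- g$z_base - g$ctr[3]
  t_cap <- ifelse(dz > 1e-9, zb / dz, Inf)
  R_ed <- pmin(t_ell, t_cap)
  # surface long-axis fraction of the ray exit point (cap rays -> base)
  z_surf <- pmin(R_ed, t_ell) * dz
  vfrac <- pmin(pmax((z_surf + g$b) / (zb + g$b), 0), 1)
  az <- atan2(dy, dx) * 180 / pi
  s_es <- array(.es_scale(spec, as.vector(az), as.vector(vfrac)), dm)

  masks <- vector("list", spec$n_frames)
  volumes <- vector("list", spec$n_frames)
  vox_ml <- prod(spec$voxel_size) / 1000
  withr::with_seed(spec$seed, {
    for (tfr in seq_len(spec$n_frames)) {
      s_t <- 1 - beta[tfr] * (1 - s_es)
      m <- nz & (r <= s_t * R_ed)
      vol <- array(spec$background_hu, dm)
      nin <- sum(m)
      vol[m] <- spec$blood_hu +
        if (spec$noise_sd > 0) stats::rnorm(nin, 0, spec$noise_sd) else 0
      masks[[tfr]] <- m
      volumes[[tfr]] <- vol
    }
  })
  volumes_ml <- vapply(masks, function(m) sum(m) * vox_ml, numeric(1))

  meshes <- vector("list", spec$n_frames)
  ed_mesh <- .phantom_mesh_ed(spec, n_az, n_long)
  for (tfr in seq_len(spec$n_frames)) {
    s_t <- 1 - beta[tfr] * (1 - ed_mesh$vertex_s_es)
    verts <- ed_mesh$vertices_centered * s_t  # recycled per coordinate row-wise
    verts <- sweep(verts, 2, g$ctr, "+")
    meshes[[tfr]] <- endo_mesh(verts, ed_mesh$faces, frame_index = tfr,
                               uv = ed_mesh$uv)
  }
  truth_rsct <- .es_scale(spec, ed_mesh$face_az, ed_mesh$face_v)^2 - 1

  structure(list(volumes = volumes, masks = masks, meshes = meshes,
                 truth_rsct = truth_rsct,
                 ed_index = 1L, es_index = es_index,
                 volumes_ml = volumes_ml,
                 lvef = (max(volumes_ml) - min(volumes_ml)) / max(volumes_ml),
                 spec = spec),
            class = "phantom_study")
}

# ED mesh on the lateral (endocardial) surface of the truncated ellipsoid.
# Rows sit at long fractions (j + 0.5) / (n_long + 1), avoiding the apex pole.
.phantom_mesh_ed <- function(spec, n_az, n_long) {
  g <- .phantom_geom(spec)
  vfr <- (seq_len(n_long + 1L) - 0.5) / (n_long + 1L)
  phi <- (seq_len(n_az) - 1L) * 360 / n_az
  uv <- expand.grid(az = phi, v = vfr)      # azimuth fastest
  z <- g$z_apex + uv$v * (g$z_base - g$z_apex) - g$ctr[3]
  rho <- g$a * sqrt(pmax(1 - (z / g$b)^2, 0))
  verts <- cbind(rho * cos(uv$az * pi / 180), rho * sin(uv$az * pi / 180), z)
  nv <- n_az
  faces <- NULL
  fi <- list()
  for (j in seq_len(n_long)) {
    base0 <- (j - 1L) * nv
    i <- seq_len(nv)
    inext <- c(seq_len(nv - 1L) + 1L, 1L)
    v00 <- base0 + i; v10 <- base0 + inext
    v01 <- base0 + nv + i; v11 <- base0 + nv + inext
    fi[[j]] <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  }
  faces <- do.call(rbind, fi)
  # face parameter centres, wrap-aware in azimuth
  face_az <- numeric(nrow(faces)); face_v <- numeric(nrow(faces))
  uaz <- uv$az[faces[, 1]]
  d2 <- ((uv$az[faces[, 2]] - uaz + 180) %% 360) - 180
  d3 <- ((uv$az[faces[, 3]] - uaz + 180) %% 360) - 180
  face_az <- (uaz + (d2 + d3) / 3) %% 360
  face_v <- (uv$v[faces[, 1]] + uv$v[faces[, 2]] + uv$v[faces[, 3]]) / 3
  list(vertices_centered = verts, faces = faces,
       vertex_s_es = .es_scale(spec, uv$az, uv$v),
       face_az = face_az, face_v = face_v, uv = uv)
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("phantom 4DCT study:", x$spec$n_frames, "frames,",
      paste(x$spec$grid_shape, collapse = "x"), "voxels\n")
  cat(sprintf("  ED frame %d (%.1f mL), ES frame %d (%.1f mL), LVEF %.2f\n",
              x$ed_index, x$volumes_ml[x$ed_index],
              x$es_index, x$volumes_ml[x$es_index], x$lvef))
  cat("  defects:", length(x$spec$defects), "\n")
  invisible(x)
}
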