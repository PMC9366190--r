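test_that("ED/ES detection and LVEF follow their definitions", {
  expect_equal(find_ed_es(c(120, 100, 60, 80)), list(ed_index = 1L,
                                                     es_index = 3L))
  expect_equal(find_ed_es(c(100, 120, 60, 80))$ed_index, 2L)
  expect_error(find_ed_es(rep(100, 5)), "constant")
  expect_error(find_ed_es(c(100, 90)), "4 frames")
  expect_equal(compute_lvef(120, 60), 0.5)
  expect_equal(compute_lvef(100, 100), 0)
  expect_equal(compute_lvef(100, 30), 0.7)
  expect_error(compute_lvef(100, 110), "exceeds")
})

test_that("mesh extraction recovers a sphere's area and rejects bad masks", {
  mask <- sphere_mask(20, grid = 56L, vox = 1.25)
  mesh <- extract_endocardial_mesh(mask, 1.25, n_az = 120L, n_long = 90L)
  expect_lt(abs(sum(mesh$face_areas) - 4 * pi * 20^2) / (4 * pi * 20^2), 0.05)
  expect_true(all(mesh$face_areas > 0))
  expect_error(extract_endocardial_mesh(array(FALSE, c(8, 8, 8)), 1),
               "empty")
  two <- array(FALSE, c(24, 24, 24))
  two[3:8, 3:8, 3:8] <- TRUE
  two[15:21, 15:21, 15:21] <- TRUE
  expect_error(extract_endocardial_mesh(two, 1), "2 large connected")
})

test_that("correspondence is identity on shared topology and area-consistent on remeshes", {
  st <- generate_study(small_spec(seed = 20L))
  corr <- establish_correspondence(st$meshes[[1]], st$meshes[[st$es_index]])
  expect_true(corr$identity)
  expect_equal(corr$mapping, seq_len(nrow(st$meshes[[1]]$faces)))
  # sphere vs scaled sphere, remeshed with a different parameterisation:
  # rotate the azimuth origin and reorder the face list so no shared
  # topology can be assumed
  m1 <- extract_endocardial_mesh(sphere_mask(20, 56L, 1.25), 1.25,
                                 n_az = 60L, n_long = 40L)
  m2e <- extract_endocardial_mesh(sphere_mask(16, 56L, 1.25), 1.25,
                                  n_az = 60L, n_long = 40L)
  rot <- pi / 7
  R <- rbind(c(cos(rot), -sin(rot), 0), c(sin(rot), cos(rot), 0), c(0, 0, 1))
  ctr <- colMeans(m2e$vertices)
  perm <- c(seq(2, nrow(m2e$faces)), 1L)
  m2 <- endo_mesh(sweep(sweep(m2e$vertices, 2, ctr) %*% t(R), 2, ctr, "+"),
                  m2e$faces[perm, ])
  corr2 <- establish_correspondence(m1, m2)
  expect_false(corr2$identity)
  ok <- !is.na(corr2$mapping)
  ratio <- sum(m2$face_areas[corr2$mapping[ok]]) / sum(m1$face_areas[ok])
  expect_lt(abs(ratio - (16 / 20)^2), 0.08)
})

test_that("RS_CT equals the area ratio minus one, with rigid-motion zero", {
  st <- generate_study(small_spec(seed = 21L))
  mesh <- st$meshes[[1]]
  corr <- establish_correspondence(mesh, mesh)
  rs0 <- compute_rsct(mesh, mesh, corr)
  expect_true(all(abs(rs0$per_face) < 1e-12))
  # rigid-body motion leaves RS_CT at zero
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- endo_mesh(mesh$vertices %*% t(R) + 5, mesh$faces)
  rs_rigid <- compute_rsct(mesh, moved, establish_correspondence(mesh, moved))
  expect_lt(max(abs(rs_rigid$per_face)), 1e-9)
  # uniform scale s gives s^2 - 1 exactly
  scaled <- endo_mesh(mesh$vertices * 0.8, mesh$faces)
  rs_s <- compute_rsct(mesh, scaled, establish_correspondence(mesh, scaled))
  expect_equal(unname(rs_s$per_face), rep(0.8^2 - 1, nrow(mesh$faces)),
               tolerance = 1e-9)
  expect_true(all(rs_s$per_face >= -1))
})

test_that("per-vertex RS_CT is the mean over adjacent faces", {
  st <- generate_study(small_spec(seed = 22L))
  mesh <- st$meshes[[1]]
  rs <- rsct_map(st$truth_rsct, mesh)
  v <- 200L
  adj <- which(rowSums(mesh$faces == v) > 0)
  expect_equal(rs$per_vertex[v], mean(rs$per_face[adj]))
})

test_that("mask-derived RS_CT matches the analytic oracle on phantoms", {
  # global contraction: closed form s^2 - 1 everywhere
  sp <- small_spec(seed = 23L, grid = 48L, vox = 2)
  st <- generate_study(sp)
  m_ed <- extract_endocardial_mesh(st$masks[[1]], 2)
  m_es <- extract_endocardial_mesh(st$masks[[st$es_index]], 2)
  rs <- compute_rsct(m_ed, m_es, establish_correspondence(m_ed, m_es))
  err <- abs(rs$per_face - (sp$global_contraction^2 - 1))
  expect_lt(stats::median(err), 0.03)
  # akinetic sector: the non-tracking mask path recovers the piecewise
  # pattern with a known longitudinal bias in the static sector (rows are
  # placed by whole-meridian arc length, which the contracting ends shorten)
  # - the bias stays far from the -0.20 impairment threshold
  spd <- small_spec(defects = list(defect_spec(0, 120, c(0.15, 0.85), 1)),
                    seed = 24L, grid = 48L, vox = 2)
  std <- generate_study(spd)
  ctr <- (colMeans(which(std$masks[[1]], arr.ind = TRUE)) - 1) * 2
  d_ed <- extract_endocardial_mesh(std$masks[[1]], 2)
  d_es <- extract_endocardial_mesh(std$masks[[std$es_index]], 2,
                                   axis_xy = ctr[1:2])
  drs <- compute_rsct(d_ed, d_es, establish_correspondence(d_ed, d_es))
  fa <- d_ed$uv$az[d_ed$faces[, 1]]
  fv <- d_ed$uv$v[d_ed$faces[, 1]]
  daz <- abs(((fa + 180) %% 360) - 180)
  core <- daz < 40 & fv > 0.3 & fv < 0.7
  remote <- daz > 80 & fv > 0.3 & fv < 0.7
  core_med <- stats::median(drs$per_face[core])
  remote_med <- stats::median(drs$per_face[remote])
  expect_gt(core_med, -0.15)                      # akinetic stays impaired
  expect_lt(stats::median(abs(drs$per_face[remote] - (0.8^2 - 1))), 0.04)
  expect_gt(core_med - remote_med, 0.2)           # clear sector contrast
})

test_that("RS_CT projection and view labels apply the stated thresholds", {
  st <- generate_study(small_spec(seed = 25L))
  mesh <- st$meshes[[1]]
  fr <- render_frame(st$volumes[[1]], view_table()[1, ], window_setting(520),
                     st$spec$voxel_size, npix = 64L, mesh = mesh)
  nfaces <- nrow(mesh$faces)
  # all faces at -0.36: nothing abnormal
  p1 <- project_rsct_to_view(rsct_map(rep(-0.36, nfaces), mesh), fr)
  expect_equal(p1$n_abnormal, 0L)
  expect_false(label_view(p1)$abnormal)
  # threshold is inclusive: exactly -0.20 is abnormal everywhere visible
  p2 <- project_rsct_to_view(rsct_map(rep(-0.20, nfaces), mesh), fr)
  expect_equal(p2$n_abnormal, p2$n_visible)
  expect_true(label_view(p2)$abnormal)
  # fraction threshold is strict at 0.35
  fake <- list(abnormal = NULL, n_visible = 100L, n_abnormal = 35L)
  class(fake) <- "projected_rsct"
  expect_false(label_view(fake)$abnormal)
  fake$n_abnormal <- 36L
  expect_true(label_view(fake)$abnormal)
  empty <- list(abnormal = NULL, n_visible = 0L, n_abnormal = 0L)
  class(empty) <- "projected_rsct"
  expect_error(label_view(empty), "visible")
})

test_that("a foreground defect is more abnormal than its opposite view", {
  spd <- small_spec(defects = list(defect_spec(30, 120, c(0.1, 0.9), 1)),
                    seed = 26L)
  st <- generate_study(spd)
  lab <- label_phantom_study(st, npix = 64L)
  # view 0 faces azimuth 30 (the defect); view 3 faces azimuth 210
  expect_gt(lab$abnormal_fractions[1], lab$abnormal_fractions[4])
})

test_that("study labels count abnormal videos against the threshold", {
  mk <- function(flags) lapply(flags, function(f)
    structure(list(abnormal = f, abnormal_fraction = NA_real_),
              class = "video_label"))
  expect_true(label_study(mk(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                               FALSE)))$abnormal)
  expect_false(label_study(mk(c(TRUE, FALSE, FALSE, FALSE, FALSE,
                                FALSE)))$abnormal)
  expect_false(label_study(mk(rep(FALSE, 6)))$abnormal)
  expect_error(label_study(mk(rep(FALSE, 5))), "6 video labels")
  # threshold 1 is at least as sensitive as 2, which beats 3
  flags <- mk(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(label_study(flags, threshold = 1L)$abnormal)
  expect_true(label_study(flags, threshold = 2L)$abnormal)
  expect_false(label_study(flags, threshold = 3L)$abnormal)
})

test_that("severity increases never flip a study abnormal -> normal", {
  prev_n <- -1L
  for (sev in c(0.4, 0.7, 1)) {
    spd <- small_spec(defects = list(defect_spec(30, 150, c(0.1, 0.9), sev)),
                      seed = 27L)
    lab <- label_phantom_study(generate_study(spd), npix = 64L)
    expect_gte(lab$study_label$n_ab_videos, prev_n)
    prev_n <- lab$study_label$n_ab_videos
  }
})
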