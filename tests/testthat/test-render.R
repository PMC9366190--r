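test_that("window level is the ROI-local mean with fixed 150 HU width", {
  dm <- c(24L, 24L, 24L)
  vol <- array(516, dm)
  mask <- array(TRUE, dm)
  w <- compute_window_level(vol, mask, 2)
  expect_equal(w$level, 516)
  expect_equal(w$width, 150)
  # ROI-local: 500 near the centroid, 600 elsewhere
  vol2 <- array(600, dm)
  ctr <- round((dm + 1) / 2)
  sel <- as.matrix(expand.grid(ctr[1] + (-2:2), ctr[2] + (-2:2),
                               ctr[3] + (-2:2)))
  vol2[sel] <- 500
  w2 <- compute_window_level(vol2, mask, 2, roi_radius_mm = 4)
  expect_equal(w2$level, 500)
  expect_error(compute_window_level(vol, array(FALSE, dm), 2), "empty")
})

test_that("rendering a blank volume yields a blank image and empty visibility", {
  vol <- array(0, c(20L, 20L, 20L))
  fr <- render_frame(vol, view_table()[1, ], window_setting(520), 2,
                     npix = 32L)
  expect_true(all(fr$image == 0))
  expect_true(all(is.na(fr$visibility)))
})

test_that("a solid sphere renders as a disk of the analytic projected size", {
  grid <- 48L; vox <- 1.5; radius <- 20
  mask <- sphere_mask(radius, grid, vox)
  vol <- array(0, rep(grid, 3L))
  vol[mask] <- 520
  ctr <- (grid - 1) * vox / 2
  fr <- render_frame(vol, view_table()[1, ], window_setting(520), vox,
                     center = rep(ctr, 3), long_axis_mm = 2 * radius,
                     npix = 128L)
  sil <- fr$image > 0.05
  # perspective projection of a sphere: occluding contour at
  # r_app = R * D / sqrt(D^2 - R^2) in the object plane, scaled to pixels
  D <- 3 * 2 * radius
  frame_half_mm <- 0.5 * 2 * radius / 0.8
  r_pix <- radius * D / sqrt(D^2 - radius^2) / frame_half_mm * 64
  expect_lt(abs(sum(sil) - pi * r_pix^2) / (pi * r_pix^2), 0.05)
  # visibility: present within the silhouette only once a mesh is supplied
  mesh <- extract_endocardial_mesh(mask, vox)
  fr2 <- render_frame(vol, view_table()[1, ], window_setting(520), vox,
                      center = rep(ctr, 3), long_axis_mm = 2 * radius,
                      npix = 128L, mesh = mesh)
  vis <- !is.na(fr2$visibility)
  expect_true(all(fr2$image[vis] > 0))
  expect_gt(sum(vis), 0.5 * sum(sil))
})

test_that("windowing is shift-invariant in HU", {
  st <- generate_study(small_spec(seed = 9L))
  vol <- st$volumes[[1]]
  vt <- view_table()
  f1 <- render_frame(vol, vt[3, ], window_setting(520), st$spec$voxel_size,
                     npix = 48L)
  f2 <- render_frame(vol + 200, vt[3, ], window_setting(720),
                     st$spec$voxel_size, npix = 48L)
  expect_lt(max(abs(f1$image - f2$image)), 1e-9)
})

test_that("rotating the phantom by -60 degrees maps view n to view n+1", {
  st <- generate_study(small_spec(
    defects = list(defect_spec(45, 130, c(0.1, 0.9), 1)), seed = 10L))
  vol <- st$volumes[[1]]
  vox <- st$spec$voxel_size
  win <- window_setting(520)
  vt <- view_table()
  rot <- rotate_volume_z(vol, -60, vox, fill = 0)
  for (n in c(1L, 4L)) {
    a <- render_frame(rot, vt[n, ], win, vox, npix = 64L)$image
    b <- render_frame(vol, vt[n + 1L, ], win, vox, npix = 64L)$image
    # interpolation tolerance: compare bulk of pixels
    expect_lt(stats::quantile(abs(a - b), 0.95), 0.2)
    expect_lt(mean(abs(a - b)), 0.03)
  }
})

test_that("render_video produces one frame per input and validates length", {
  st <- generate_study(small_spec(seed = 11L, n_frames = 6L))
  win <- window_setting(520)
  vid <- render_video(st$volumes, view_table()[2, ], win,
                      st$spec$voxel_size, npix = 32L)
  expect_length(vid$frames, 6L)
  expect_error(render_video(st$volumes[1:3], view_table()[2, ], win,
                            st$spec$voxel_size, npix = 32L), "4 frames")
  # a static volume renders identical frames
  vid2 <- render_video(rep(st$volumes[1], 4), view_table()[2, ], win,
                       st$spec$voxel_size, npix = 32L)
  expect_identical(vid2$frames[[1]]$image, vid2$frames[[4]]$image)
})

test_that("input-frame selection follows the even-spacing rule", {
  st <- generate_study(small_spec(seed = 12L, n_frames = 10L))
  win <- window_setting(520)
  vid <- render_video(st$volumes, view_table()[1, ], win,
                      st$spec$voxel_size, npix = 32L)
  f <- select_input_frames(vid, 1L, 10L)
  expect_equal(attr(f, "frame_indices"), c(1, 4, 7, 10))
  expect_equal(dim(f[[1]]), c(299L, 299L))
  f2 <- select_input_frames(vid, 1L, 4L)
  expect_equal(attr(f2, "frame_indices"), 1:4)
  expect_warning(f3 <- select_input_frames(vid, 1L, 2L), "interior")
  expect_equal(attr(f3, "frame_indices"), c(1, 1, 2, 2))
  expect_error(select_input_frames(vid, 3L, 3L), "differ")
})

test_that("every mid-wall face is visible in at least one of the six views", {
  # mesh resolution chosen below the pixel count so faces subtend >= 1 pixel
  st <- generate_study(small_spec(seed = 13L), n_az = 48L, n_long = 24L)
  mesh <- st$meshes[[1]]
  win <- window_setting(520)
  seen <- integer(0)
  for (v in seq_len(6L)) {
    fr <- render_frame(st$volumes[[1]], view_table()[v, ], win,
                       st$spec$voxel_size, npix = 96L, mesh = mesh)
    seen <- union(seen, fr$visibility[!is.na(fr$visibility)])
  }
  mid <- which(st$meshes[[1]]$uv$v[mesh$faces[, 1]] > 0.3 &
               st$meshes[[1]]$uv$v[mesh$faces[, 1]] < 0.7)
  expect_gt(mean(mid %in% seen), 0.99)
})
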