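test_that("pinhole projection follows the distortion model", {
  intr <- default_intrinsics()
  board <- checkerboard()
  # on-axis point lands on the principal point
  p <- project_points(intr, rigid_transform(), matrix(c(0, 0, 1000), 1))
  expect_equal(as.numeric(p), c(intr$cx, intr$cy), tolerance = 1e-12)
  # doubling fx doubles the x offset from cx
  intr2 <- camera_intrinsics(1600, 800, 640, 360)
  q <- matrix(c(50, 30, 900), 1)
  p1 <- project_points(intr, rigid_transform(), q)
  p2 <- project_points(intr2, rigid_transform(), q)
  expect_equal(p2[1] - intr$cx, 2 * (p1[1] - intr$cx), tolerance = 1e-10)
  expect_equal(p2[2], p1[2])
  # radial distortion against a direct scalar evaluation: normalized radius
  # 0.5 with k1 = -0.1 contracts radially by (1 + k1 * 0.25)
  intr_d <- camera_intrinsics(800, 800, 640, 360, k1 = -0.1)
  pt <- matrix(c(0.3, 0.4, 1), 1) * 1000   # normalized (0.3, 0.4), r = 0.5
  pd <- project_points(intr_d, rigid_transform(), pt)
  scale <- 1 + (-0.1) * 0.25
  expect_equal(as.numeric(pd),
               c(640 + 800 * 0.3 * scale, 360 + 800 * 0.4 * scale),
               tolerance = 1e-10)
  # points behind the camera refuse to project
  expect_error(project_points(intr, rigid_transform(), matrix(c(0, 0, -5), 1)),
               "projection-domain")
})

test_that("homography estimation recovers known mappings", {
  # identity mapping of the unit square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- estimate_homography(sq, sq)
  expect_equal(H, diag(3), tolerance = 1e-8)
  # synthetic known homography, exact recovery up to scale
  set.seed(21)
  for (i in 1:10) {
    Htrue <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    Htrue[3, 3] <- 1
    xy <- matrix(runif(40, -50, 50), ncol = 2)
    uv <- depthreg:::apply_homography(Htrue, xy)
    Hest <- estimate_homography(xy, uv)
    expect_lt(max(abs(Hest / Hest[3, 3] - Htrue)), 1e-8)
  }
  # minimal exact case: 4 points, zero residual
  xy4 <- matrix(runif(8, -30, 30), 4)
  uv4 <- depthreg:::apply_homography(Htrue, xy4)
  H4 <- estimate_homography(xy4, uv4)
  expect_lt(max(abs(depthreg:::apply_homography(H4, xy4) - uv4)), 1e-7)
  expect_error(estimate_homography(xy4[1:3, ], uv4[1:3, ]), "rank-deficiency")
})

test_that("calibration recovers intrinsics from noise-free views", {
  truth <- default_intrinsics()
  board <- checkerboard()
  obs <- simulate_calibration_views(truth, board, n_views = 8,
                                    corner_noise_px = 0, seed = 22)
  cal <- zhang_calibrate(obs, board, width = truth$width, height = truth$height)
  expect_lt(abs(cal$intrinsics$fx - truth$fx), 0.1)
  expect_lt(abs(cal$intrinsics$fy - truth$fy), 0.1)
  expect_lt(cal$mean_reprojection_px, 1e-4)
  # per-view poses must reproject exactly
  expect_true(all(cal$per_view_error_px < 1e-4))
  expect_error(zhang_calibrate(obs[1:2], board), "ill-conditioned")
})

test_that("calibration error tracks the injected corner noise", {
  truth <- default_intrinsics()
  board <- checkerboard()
  obs <- simulate_calibration_views(truth, board, n_views = 8,
                                    corner_noise_px = 0.2, seed = 23)
  cal <- zhang_calibrate(obs, board, width = truth$width, height = truth$height)
  # mean per-corner distance for 2-d gaussian residuals ~ sigma * sqrt(pi/2),
  # slightly deflated by the fitted parameters; 30% envelope around 0.2 px
  expect_gt(cal$mean_reprojection_px, 0.2 * 0.7)
  expect_lt(cal$mean_reprojection_px, 0.2 * 1.3)
  expect_lt(abs(cal$intrinsics$fx - truth$fx), 5)
})

test_that("board pose estimation inverts the projection", {
  intr <- camera_intrinsics(800, 800, 640, 360, k1 = -0.08, k2 = 0.01,
                            p1 = 5e-4, p2 = -3e-4)
  board <- checkerboard()
  set.seed(24)
  obs <- simulate_calibration_views(intr, board, n_views = 4,
                                    corner_noise_px = 0, seed = 24)
  poses <- attr(obs, "poses")
  for (i in seq_along(obs)) {
    est <- estimate_board_pose(intr, board, obs[[i]])
    expect_lt(rotation_geodesic_deg(est, poses[[i]]), 1e-5)
    expect_lt(trans_err_mm(est, poses[[i]]), 1e-4)
  }
  # frontoparallel board on axis at 400 mm
  ctr <- colMeans(board$corner_points)
  pose_fp <- rigid_transform(diag(3), c(-ctr[1], -ctr[2], 400))
  obs_fp <- project_board(intr, pose_fp, board)
  est_fp <- estimate_board_pose(intr, board, obs_fp)
  expect_equal(est_fp$t[3], 400, tolerance = 1e-3)
  expect_lt(rotation_geodesic_deg(est_fp, pose_fp), 1e-4)
})

test_that("board pose is stable under moderate corner noise", {
  intr <- default_intrinsics()
  board <- checkerboard()
  obs <- simulate_calibration_views(intr, board, n_views = 1,
                                    corner_noise_px = 0, seed = 25)
  pose <- attr(obs, "poses")[[1]]
  clean <- obs[[1]]$image_points
  set.seed(25)
  errs <- replicate(100, {
    noisy <- corner_observation(clean + matrix(rnorm(length(clean), 0, 0.5),
                                               ncol = 2))
    est <- estimate_board_pose(intr, board, noisy)
    trans_err_mm(est, pose)
  })
  expect_lt(max(errs), 5)
})

test_that("reprojection error statistics match a per-corner loop", {
  intr <- default_intrinsics()
  board <- checkerboard()
  obs <- simulate_calibration_views(intr, board, n_views = 1,
                                    corner_noise_px = 0, seed = 26)
  pose <- attr(obs, "poses")[[1]]
  # exact observation: zero error
  expect_equal(unname(reprojection_error_px(intr, pose, board, obs[[1]])),
               c(0, 0))
  # uniform +1 px shift in x: mean 1, sd 0
  shifted <- corner_observation(sweep(obs[[1]]$image_points, 2, c(1, 0), "+"))
  e <- reprojection_error_px(intr, pose, board, shifted)
  expect_equal(unname(e), c(1, 0), tolerance = 1e-12)
  # random perturbation against an explicit loop
  set.seed(26)
  pert <- obs[[1]]$image_points + matrix(rnorm(2 * nrow(board$corner_points)),
                                         ncol = 2)
  ob <- corner_observation(pert)
  e2 <- reprojection_error_px(intr, pose, board, ob)
  proj <- project_points(intr, pose, board$corner_points)
  d <- numeric(nrow(proj))
  for (i in seq_len(nrow(proj))) {
    d[i] <- sqrt(sum((proj[i, ] - pert[i, ])^2))
  }
  expect_equal(e2[["mean"]], mean(d), tolerance = 1e-12)
  expect_equal(e2[["sd"]], sd(d), tolerance = 1e-12)
})

test_that("intrinsics and corner files round-trip", {
  intr <- camera_intrinsics(812.3, 799.1, 644.2, 358.8, k1 = -0.11,
                            k2 = 0.021, k3 = -0.002, p1 = 1e-4, p2 = -2e-4)
  f <- tempfile(fileext = ".yaml")
  write_intrinsics(intr, f)
  back <- read_intrinsics(f)
  expect_equal(unclass(back), unclass(intr))
  board <- checkerboard()
  obs <- simulate_calibration_views(default_intrinsics(), board, n_views = 3,
                                    corner_noise_px = 0.1, seed = 27)
  cf <- tempfile(fileext = ".csv")
  write_corners(obs, cf)
  back_obs <- read_corners(cf)
  expect_length(back_obs, 3)
  for (o in obs) {
    expect_equal(back_obs[[o$capture_id]]$image_points, o$image_points,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(checkerboard(5, 5), "inner_rows")
})
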