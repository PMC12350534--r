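test_that("phantom head meets the anthropometric targets", {
  sc <- test_scene()
  expect_equal(measure_bigonial_width_mm(sc), 118, tolerance = 2 / 118)
  expect_equal(measure_nose_length_mm(sc), 50, tolerance = 2 / 50)
  expect_equal(measure_alar_base_mm(sc), 35, tolerance = 2 / 35)
  expect_identical(nrow(sc$fiducials), 8L)
  expect_setequal(unique(sc$region_labels),
                  c("face", "scalp", "craniotomy", "other"))
  expect_true(all(abs(sqrt(rowSums(sc$normals^2)) - 1) < 1e-9))
  expect_error(generate_phantom_head(point_spacing_mm = 10), "argument error")
})

test_that("phantom generation is deterministic and density scales", {
  a <- generate_phantom_head(seed = 7, point_spacing_mm = 3)
  b <- generate_phantom_head(seed = 7, point_spacing_mm = 3)
  expect_identical(a$surface_points, b$surface_points)
  expect_identical(a$fiducials, b$fiducials)
  c_ <- generate_phantom_head(seed = 7, point_spacing_mm = 1.5)
  ratio <- nrow(c_$surface_points) / nrow(a$surface_points)
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("craniotomy region is labelled, boxed and recessed", {
  sc <- test_scene()
  crani <- sc$surface_points[sc$region_labels == "craniotomy", ]
  expect_gt(nrow(crani), 50)
  expect_true(all(crani >= matrix(sc$craniotomy_box[1, ], nrow(crani), 3,
                                  byrow = TRUE)))
  expect_true(all(crani <= matrix(sc$craniotomy_box[2, ], nrow(crani), 3,
                                  byrow = TRUE)))
  # patch diameter close to the requested 70 mm
  ext <- apply(crani, 2, function(v) diff(range(v)))
  expect_lt(max(ext), 75)
  expect_gt(max(ext), 55)
})

test_that("tracked-pose jitter has the requested statistics", {
  truth <- rand_tf()
  # zero noise is the identity perturbation
  expect_identical(simulate_tracked_pose(truth, tracking_noise(0, 0)), truth)
  set.seed(41)
  sig <- 0.3
  tfs <- replicate(10000, simulate_tracked_pose(
    truth, tracking_noise(0.1, sig)), simplify = FALSE)
  for (tf in tfs[1:50]) expect_true(is_rigid_transform(tf))
  dn <- vapply(tfs, function(tf) sqrt(sum((tf$t - truth$t)^2)), numeric(1))
  # ||N(0, sig I3)|| has mean sig * sqrt(2/pi) * sqrt(2) * gamma(2)/gamma(1.5);
  # compare against an empirical reference simulation instead of the formula
  ref <- sqrt(rowSums(matrix(rnorm(30000, 0, sig), ncol = 3)^2))
  expect_equal(mean(dn), mean(ref), tolerance = 0.05)
  ang <- vapply(tfs, function(tf) rotation_geodesic_deg(tf, truth), numeric(1))
  expect_equal(mean(ang), mean(abs(rnorm(10000, 0, 0.1))), tolerance = 0.05)
})

test_that("zero-noise depth capture lies exactly on the phantom surface", {
  sc <- test_scene()
  face_ctr <- colMeans(sc$surface_points[sc$region_labels == "face", ])
  pose <- depthreg:::look_at_pose(face_ctr + c(30, 440, 90), face_ctr)
  cl <- simulate_depth_capture(sc, pose, zero_preset(), seed = 3)
  w <- transform_points(pose, cl)
  nn <- nearest_neighbors(w, sc$surface_points)
  expect_lt(max(nn$distance), 1e-9)
  expect_gt(nrow(cl), 1000)
  expect_true(!is.null(attr(cl, "labels")))
  # determinism
  cl2 <- simulate_depth_capture(sc, pose, zero_preset(), seed = 3)
  expect_identical(unclass(cl), unclass(cl2))
})

test_that("dropout thins the cloud binomially and range gates the capture", {
  sc <- test_scene()
  face_ctr <- colMeans(sc$surface_points[sc$region_labels == "face", ])
  pose <- depthreg:::look_at_pose(face_ctr + c(0, 440, 60), face_ctr)
  base <- simulate_depth_capture(sc, pose, zero_preset(), seed = 5)
  half <- camera_noise_preset("half", 0, dropout_rate = 0.5,
                              range_min_mm = 50, range_max_mm = 2000)
  thin <- simulate_depth_capture(sc, pose, half, seed = 5)
  n <- nrow(base); k <- nrow(thin)
  expect_gt(k, n * 0.5 - 4 * sqrt(n * 0.25))
  expect_lt(k, n * 0.5 + 4 * sqrt(n * 0.25))
  # camera beyond the working range sees nothing (short-range preset at 600mm)
  d405ish <- camera_noise_preset("short", 0.4, range_min_mm = 70,
                                 range_max_mm = 500)
  pose_far <- depthreg:::look_at_pose(face_ctr + c(0, 600, 0), face_ctr)
  expect_error(simulate_depth_capture(sc, pose_far, d405ish, seed = 5),
               "visibility error")
})

test_that("axial noise moves points along the viewing ray", {
  sc <- test_scene()
  face_ctr <- colMeans(sc$surface_points[sc$region_labels == "face", ])
  pose <- depthreg:::look_at_pose(face_ctr + c(0, 430, 50), face_ctr)
  noisy_p <- camera_noise_preset("axial", 1.5, range_min_mm = 50,
                                 range_max_mm = 2000)
  cl <- simulate_depth_capture(sc, pose, noisy_p, seed = 6)
  w <- transform_points(pose, cl)
  d <- nearest_neighbors(w, sc$surface_points)$distance
  # distances to the surface scale with the injected sigma
  expect_gt(sd(d), 0.3)
  expect_lt(mean(d), 4 * 1.5)
})

test_that("builtin presets mirror the seven camera configurations", {
  ps <- builtin_presets()
  expect_length(ps, 7)
  expect_setequal(names(ps), c("d405", "d435f", "d435f-no-projector", "zed-m",
                               "zed-m-plus", "oak-d", "photoneo-s"))
  for (p in ps) {
    expect_s3_class(p, "camera_noise_preset")
    expect_gte(p$axial_sigma_mm, 0)
    expect_gte(p$dropout_rate, 0); expect_lt(p$dropout_rate, 1)
    expect_lt(p$range_min_mm, p$range_max_mm)
  }
  # projector-less variant is strictly noisier than its counterpart
  expect_gt(ps[["d435f-no-projector"]]$axial_sigma_mm,
            ps[["d435f"]]$axial_sigma_mm)
  expect_gt(ps[["zed-m"]]$axial_sigma_mm, ps[["zed-m-plus"]]$axial_sigma_mm)
  f <- tempfile(fileext = ".yaml")
  write_presets(ps, f)
  back <- read_presets(f)
  expect_equal(lapply(back, unclass), lapply(ps, unclass))
})

test_that("projector and refinement toggles decide the overlap gate", {
  sc <- test_scene()
  face_ctr <- colMeans(sc$surface_points[sc$region_labels == "face", ])
  mr_face <- sc$surface_points[sc$region_labels == "face", ]
  ps <- builtin_presets()
  set.seed(42)
  pose <- depthreg:::look_at_pose(face_ctr + c(20, 435, 80), face_ctr)
  run_one <- function(preset) {
    cl <- simulate_depth_capture(sc, pose, preset, seed = 9)
    cap <- cl[attr(cl, "labels") == "face", , drop = FALSE]
    register_face(cap, mr_face, seed = 9)$overlap_fraction
  }
  expect_gte(run_one(ps[["d435f"]]), 0.95)
  expect_lt(run_one(ps[["d435f-no-projector"]]), 0.95)
  expect_lt(run_one(ps[["oak-d"]]), 0.95)
})

test_that("scene export writes PLY, fiducials and ROI box", {
  sc <- generate_phantom_head(seed = 2, point_spacing_mm = 4)
  d <- tempfile()
  export_scene(sc, d)
  pts <- read_ply(file.path(d, "phantom.ply"))
  expect_identical(unname(pts[, 1:3]), unname(sc$surface_points))
  expect_identical(length(attr(pts, "labels")), nrow(sc$surface_points))
  fid <- read.csv(file.path(d, "fiducials.csv"))
  expect_identical(nrow(fid), 8L)
  box <- jsonlite::read_json(file.path(d, "craniotomy_box.json"),
                             simplifyVector = TRUE)
  expect_equal(box$min_mm, sc$craniotomy_box[1, ], tolerance = 1e-12)
})
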