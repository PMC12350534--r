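test_that("kd-tree nearest neighbours agree exactly with brute force", {
  set.seed(51)
  for (rep_ in 1:5) {
    q <- matrix(rnorm(600, sd = 40), 200)
    r <- matrix(rnorm(3 * sample(50:400, 1), sd = 40), ncol = 3)
    a <- nearest_neighbors(q, r, method = "kdtree")
    b <- nearest_neighbors(q, r, method = "brute")
    expect_identical(a$index, b$index)
    expect_identical(a$distance, b$distance)
  }
  # degenerate cases
  r1 <- matrix(c(1, 2, 3), 1)
  nn <- nearest_neighbors(matrix(rnorm(30), 10), r1)
  expect_true(all(nn$index == 1L))
  self <- matrix(rnorm(90), 30)
  nn2 <- nearest_neighbors(self, self)
  expect_identical(nn2$index, 1:30)
  expect_true(all(nn2$distance == 0))
  expect_error(nearest_neighbors(self, self[0, ]), "argument error")
})

test_that("voxel downsampling returns in-cell centroids", {
  set.seed(52)
  cloud <- matrix(runif(300, 0, 100), 100)
  ds <- voxel_downsample(cloud, 10)
  expect_lt(nrow(ds), nrow(cloud))
  # every centroid lies within its voxel
  expect_true(all(vapply(seq_len(nrow(ds)), function(i) {
    cell <- floor(ds[i, ] / 10)
    members <- floor(cloud / 10)
    any(apply(members, 1, function(m) all(m == cell)))
  }, logical(1))))
})

test_that("ICP recovers constructed perturbations", {
  sc <- test_scene()
  cloud <- sc$surface_points[sc$region_labels == "face", ]
  # identical clouds, identity init: exact, first iteration
  r0 <- icp_point_to_point(cloud, cloud)
  expect_lt(r0$inlier_rmse_mm, 1e-9)
  expect_lt(rotation_geodesic_deg(r0$transform, rigid_transform()), 1e-9)
  expect_equal(r0$overlap_fraction, 1)
  # 5 deg / 5 mm perturbation about the cloud centroid, identity init
  ctr <- colMeans(cloud)
  rot <- axis_rotation("z", 5)
  tstar <- rigid_transform(rot$R,
                           as.numeric(ctr - rot$R %*% ctr) + c(3, -2, 4) / sqrt(3))
  target <- transform_points(tstar, cloud)
  r1 <- icp_point_to_point(cloud, target)
  # the acos-based geodesic has a ~1e-6 deg measurement floor near zero
  expect_lt(rotation_geodesic_deg(r1$transform, tstar), 1e-5)
  expect_lt(max(abs(r1$transform$R - tstar$R)), 1e-9)
  expect_lt(trans_err_mm(r1$transform, tstar), 1e-6)
  expect_lt(r1$inlier_rmse_mm, 1e-6)
})

test_that("the ICP least-squares step never worsens its own objective", {
  sc <- test_scene()
  cloud <- sc$surface_points[sc$region_labels == "face", ]
  set.seed(53)
  for (rep_ in 1:5) {
    pert <- compose(rigid_transform(
      depthreg:::axis_angle_to_rotation(rnorm(3, 0, 0.05)), rnorm(3, 0, 5)),
      rigid_transform())
    target <- transform_points(pert, cloud) +
      matrix(rnorm(length(cloud), 0, 0.3), ncol = 3)
    res <- icp_point_to_point(cloud, target)
    h <- attr(res, "history")
    expect_true(all(h[, "rmse_after_mm"] <= h[, "rmse_before_mm"] + 1e-9))
  }
})

test_that("ICP result does not depend on point ordering", {
  sc <- test_scene()
  cloud <- sc$surface_points[sc$region_labels == "face", ]
  set.seed(54)
  pert <- rigid_transform(depthreg:::axis_angle_to_rotation(c(0.02, 0, 0.03)),
                          c(3, 1, -2))
  target <- transform_points(pert, cloud)
  r1 <- icp_point_to_point(cloud, target)
  perm_s <- sample(nrow(cloud)); perm_t <- sample(nrow(target))
  r2 <- icp_point_to_point(cloud[perm_s, ], target[perm_t, ])
  expect_lt(rotation_geodesic_deg(r1$transform, r2$transform), 1e-6)
  expect_lt(trans_err_mm(r1$transform, r2$transform), 1e-6)
})

test_that("ICP noise floor matches an independent reference implementation", {
  set.seed(55)
  sc <- test_scene()
  cloud <- sc$surface_points[sc$region_labels == "face", ]
  cloud <- cloud[sample(nrow(cloud), 800), ]
  # with isotropic sigma = 0.5 mm per axis, the distance from a point to its
  # own noisy twin has RMS sqrt(3) * sigma = 0.87 mm; the nearest-neighbour
  # distance is bounded above by that and only mildly below it at this
  # sampling density
  rmses <- replicate(10, {
    target <- cloud + matrix(rnorm(length(cloud), 0, 0.5), ncol = 3)
    icp_point_to_point(cloud, target)$inlier_rmse_mm
  })
  expect_true(all(rmses > 0.5 & rmses < 0.5 * sqrt(3) * 1.05))
  # independent reference: plain untrimmed ICP written out longhand
  target <- cloud + matrix(rnorm(length(cloud), 0, 0.5), ncol = 3)
  tf_ref <- rigid_transform()
  for (it in 1:30) {
    moved <- transform_points(tf_ref, cloud)
    nn <- nearest_neighbors(moved, target, method = "brute")
    tf_ref <- rigid_fit(cloud, target[nn$index, ])
  }
  d_ref <- nearest_neighbors(transform_points(tf_ref, cloud), target,
                             method = "brute")$distance
  ours <- icp_point_to_point(cloud, target, corr_tol_mm = 1e6,
                             corr_tol_floor_mm = 1e6)
  expect_equal(ours$inlier_rmse_mm, sqrt(mean(d_ref^2)), tolerance = 0.05)
})

test_that("RANSAC initialisation recovers gross misalignments", {
  sc <- test_scene()
  cloud <- sc$surface_points[sc$region_labels == "face", ]
  ds <- voxel_downsample(cloud, 5)
  # identical clouds: identity-equivalent result
  r_id <- ransac_global_init(cloud, cloud, seed = 1)
  expect_lt(rotation_geodesic_deg(r_id, rigid_transform()), 1e-3)
  # known gross transform: 120 degrees about a skew axis
  axis <- c(1, 1, 1) / sqrt(3)
  tstar <- rigid_transform(
    depthreg:::axis_angle_to_rotation(axis * 120 * pi / 180), c(80, -40, 120))
  target <- transform_points(tstar, cloud)
  init <- ransac_global_init(ds, target, seed = 2)
  final <- icp_point_to_point(cloud, target, init = init)
  expect_lt(rotation_geodesic_deg(final$transform, tstar), 1e-6)
  expect_lt(trans_err_mm(final$transform, tstar), 1e-6)
  # ... which ICP alone cannot do from identity: it either lands far away or
  # rejects every correspondence (the documented divergence contract)
  blind_err <- tryCatch(
    rotation_geodesic_deg(icp_point_to_point(cloud, target)$transform, tstar),
    error = function(e) Inf)
  expect_gt(blind_err, 1)
  # determinism per seed
  i1 <- ransac_global_init(ds, target, seed = 7)
  i2 <- ransac_global_init(ds, target, seed = 7)
  expect_identical(i1, i2)
})

test_that("register_face reproduces the camera pose on clean captures", {
  sc <- test_scene()
  face_ctr <- colMeans(sc$surface_points[sc$region_labels == "face", ])
  mr_face <- sc$surface_points[sc$region_labels == "face", ]
  set.seed(56)
  for (s in 1:2) {
    pose <- depthreg:::look_at_pose(face_ctr + c(rnorm(1, 30, 40), 440,
                                                 rnorm(1, 90, 40)), face_ctr)
    cl <- simulate_depth_capture(sc, pose, zero_preset(), seed = s)
    cap <- cl[attr(cl, "labels") == "face", ]
    reg <- register_face(cap, mr_face, seed = s)
    expect_lt(rotation_geodesic_deg(reg$transform, pose), 1e-5)
    expect_lt(trans_err_mm(reg$transform, pose), 1e-6)
    expect_equal(reg$overlap_fraction, 1)
  }
  expect_error(register_face(mr_face[1:50, ], mr_face, seed = 1),
               "argument error")
})

test_that("chain_to_tracking composes the frame chain correctly", {
  # all-identity inputs give the identity
  id <- chain_to_tracking(rigid_transform(), rigid_transform(),
                          rigid_transform())
  expect_lt(rotation_geodesic_deg(id, rigid_transform()), 1e-12)
  set.seed(57)
  # simulator ground truth: patient pose recovered through the full chain
  t_w_p <- rand_tf()        # phantom in tracking frame
  t_p_o <- rand_tf()        # camera optical in phantom frame
  e <- small_rot_tf()       # optical -> camera body mount
  m_camera <- compose(compose(t_w_p, t_p_o), invert(e))
  reg_tf <- t_p_o           # perfect registration: camera -> patient
  est <- chain_to_tracking(reg_tf, m_camera, e)
  expect_lt(rotation_geodesic_deg(est, t_w_p), 1e-9)
  expect_lt(trans_err_mm(est, t_w_p), 1e-9)
  # a different camera placement yields the same patient pose
  t_p_o2 <- rand_tf()
  m_camera2 <- compose(compose(t_w_p, t_p_o2), invert(e))
  est2 <- chain_to_tracking(t_p_o2, m_camera2, e)
  expect_lt(trans_err_mm(est2, est), 1e-9)
})
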