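#' Pinhole camera intrinsics with Brown-Conrady distortion
#'
#' Image coordinates have their origin at the top-left pixel centre, x to the
#' right, y down, units px. All-zero distortion coefficients give an ideal
#' pinhole.
#'
#' @param fx,fy focal lengths (px), positive.
#' @param cx,cy principal point (px), inside the sensor.
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @param width,height sensor resolution (px).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0,
                              p1 = 0, p2 = 0, width = 1280, height = 720) {
  if (fx <= 0 || fy <= 0) stop("invalid intrinsics: fx, fy must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    stop("invalid intrinsics: principal point outside sensor")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> fx=%.2f fy=%.2f cx=%.2f cy=%.2f  %dx%d px\n",
              x$fx, x$fy, x$cx, x$cy, as.integer(x$width), as.integer(x$height)))
  cat(sprintf("  distortion k=(%.4g, %.4g, %.4g) p=(%.4g, %.4g)\n",
              x$k1, x$k2, x$k3, x$p1, x$p2))
  invisible(x)
}

#' Planar checkerboard target geometry
#'
#' Inner-corner grid on the z = 0 plane of the board frame, row-major from the
#' board origin. Unequal row and column counts disambiguate the board's
#' orientation.
#'
#' @param inner_rows,inner_cols inner corner counts (both >= 3, unequal).
#' @param square_mm square edge length (mm).
#' @return An object of class `checkerboard` with a `corner_points` matrix
#'   ((rows*cols) x 3 mm, z = 0).
#' @export
checkerboard <- function(inner_rows = 7, inner_cols = 10, square_mm = 25) {
  stopifnot(inner_rows >= 3, inner_cols >= 3)
  if (inner_rows == inner_cols) {
    stop("checkerboard: inner_rows must differ from inner_cols")
  }
  grid <- expand.grid(col = seq_len(inner_cols) - 1L,
                      row = seq_len(inner_rows) - 1L)
  pts <- cbind(grid$col * square_mm, grid$row * square_mm, 0)
  structure(list(inner_rows = inner_rows, inner_cols = inner_cols,
                 square_mm = square_mm, corner_points = pts),
            class = "checkerboard")
}

#' One set of detected checkerboard corners
#' @param image_points (rows*cols) x 2 matrix of pixel coordinates.
#' @param capture_id identifier string.
#' @return An object of class `corner_observation`.
#' @export
corner_observation <- function(image_points, capture_id = "capture") {
  image_points <- as.matrix(image_points)
  stopifnot(ncol(image_points) == 2L)
  structure(list(image_points = image_points, capture_id = capture_id),
            class = "corner_observation")
}

# distort normalized coordinates (n x 2) by the Brown-Conrady model
distort_normalized <- function(xy, intr) {
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  xd <- x * radial + 2 * intr$p1 * x * y + intr$p2 * (r2 + 2 * x^2)
  yd <- y * radial + intr$p1 * (r2 + 2 * y^2) + 2 * intr$p2 * x * y
  cbind(xd, yd)
}

# invert the distortion by fixed-point iteration on normalized coords
undistort_normalized <- function(xy, intr, iters = 20L) {
  und <- xy
  for (i in seq_len(iters)) {
    d <- distort_normalized(und, intr)
    und <- und + (xy - d)
  }
  und
}

#' Project checkerboard corners into an image
#'
#' Standard pinhole projection with Brown-Conrady distortion: board corners
#' are mapped into the optical frame by `pose` (board-to-camera), normalised
#' by depth, distorted, then scaled and offset by the focal lengths and
#' principal point.
#'
#' @param intr `camera_intrinsics`.
#' @param pose `rigid_transform`, board frame to camera optical frame.
#' @param board `checkerboard`.
#' @param capture_id identifier for the resulting observation.
#' @return A `corner_observation`.
#' @export
project_board <- function(intr, pose, board, capture_id = "projected") {
  corner_observation(project_points(intr, pose, board$corner_points),
                     capture_id = capture_id)
}

#' @rdname project_board
#' @param points N x 3 matrix in the source frame of `pose`.
#' @return `project_points` returns an N x 2 matrix of pixel coordinates.
#' @export
project_points <- function(intr, pose, points) {
  pc <- transform_points(pose, points)
  if (any(pc[, 3] <= 0)) {
    stop("projection-domain error: point behind camera (z <= 0)")
  }
  xy <- pc[, 1:2, drop = FALSE] / pc[, 3]
  d <- distort_normalized(xy, intr)
  cbind(intr$fx * d[, 1] + intr$cx, intr$fy * d[, 2] + intr$cy)
}

#' Estimate a planar homography by the normalised DLT
#'
#' Maps board-plane coordinates (mm) to image coordinates (px) with a 3x3
#' homography scaled so that `H[3, 3] = 1`. Both point sets are Hartley-
#' normalised before the linear solve.
#'
#' @param board_xy N x 2 board-plane coordinates (mm).
#' @param image_points N x 2 pixel coordinates.
#' @return 3 x 3 homography matrix.
#' @export
estimate_homography <- function(board_xy, image_points) {
  board_xy <- as.matrix(board_xy); image_points <- as.matrix(image_points)
  n <- nrow(board_xy)
  stopifnot(n == nrow(image_points), ncol(board_xy) == 2L,
            ncol(image_points) == 2L)
  if (n < 4L) stop("rank-deficiency: need at least 4 point pairs")
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T_ <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3,
                 byrow = TRUE)
    list(T = T_, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  na <- norm_pts(board_xy); nb <- norm_pts(image_points)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(na$p[i, ], 1)
    u <- nb$p[i, 1]; v <- nb$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-12 * sv$d[1]) {
    stop("rank-deficiency: degenerate point configuration for homography")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nb$T) %*% Hn %*% na$T
  if (abs(H[3, 3]) < 1e-14) stop("rank-deficiency: homography has H[3,3] ~ 0")
  H / H[3, 3]
}

apply_homography <- function(H, xy) {
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Zhang's closed-form intrinsics from a set of board homographies.
zhang_closed_form <- function(Hs) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))
  }))
  if (length(Hs) < 3L) V <- rbind(V, c(0, 1, 0, 0, 0, 0)) # enforce zero skew
  sv <- svd(V)
  b <- sv$v[, ncol(sv$v)]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  if (abs(den) < 1e-18) stop("ill-conditioned: homography set near-degenerate")
  cy <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + cy * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 <= 0) stop("ill-conditioned: negative focal-length estimate")
  fx <- sqrt(lam / B11)
  fy <- sqrt(lam * B11 / den)
  skew <- -B12 * fx^2 * fy / lam
  cx <- skew * cy / fy - B13 * fx^2 / lam
  list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew)
}

# initial extrinsics from homography and K (zero distortion assumption)
pose_from_homography <- function(H, K) {
  A <- solve(K) %*% H
  lam <- 1 / sqrt(sum(A[, 1]^2))
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]
  t <- lam * A[, 3]
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  R <- orthonormalize_rotation(cbind(r1, r2, pracma_cross(r1, r2)))
  rigid_transform(R, t)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pack_pose <- function(tf) c(rotation_to_axis_angle(tf$R), tf$t)
unpack_pose <- function(p) rigid_transform(axis_angle_to_rotation(p[1:3]),
                                           p[4:6])

#' Camera calibration from checkerboard observations
#'
#' Recovers intrinsics and per-view board poses from several corner
#' observations of a planar checkerboard: closed-form intrinsics from the
#' homography constraints, followed by joint Levenberg-Marquardt refinement of
#' intrinsics, Brown-Conrady distortion and the per-view poses, minimising the
#' total squared reprojection error. The skew estimated in the closed form is
#' dropped in refinement (zero-skew model).
#'
#' @param observations list of `corner_observation` (>= 3 distinct views).
#' @param board `checkerboard`.
#' @param width,height sensor resolution for the returned intrinsics (px).
#' @param estimate_distortion logical; refine k1..k3, p1, p2 as well.
#' @return A list with `intrinsics` (`camera_intrinsics`), `poses` (list of
#'   board-to-camera `rigid_transform`), `mean_reprojection_px` and
#'   `per_view_error_px`.
#' @export
zhang_calibrate <- function(observations, board, width = 1280, height = 720,
                            estimate_distortion = TRUE) {
  if (length(observations) < 3L) {
    stop("ill-conditioned: need at least 3 views for calibration")
  }
  xy <- board$corner_points[, 1:2, drop = FALSE]
  Hs <- lapply(observations, function(o) estimate_homography(xy, o$image_points))
  cf <- zhang_closed_form(Hs)
  K <- matrix(c(cf$fx, 0, cf$cx, 0, cf$fy, cf$cy, 0, 0, 1), 3, byrow = TRUE)
  poses0 <- lapply(Hs, pose_from_homography, K = K)
  nview <- length(observations)
  nd <- if (estimate_distortion) 5L else 0L
  p0 <- c(cf$fx, cf$fy, cf$cx, cf$cy, rep(0, nd),
          unlist(lapply(poses0, pack_pose)))
  obs_mat <- lapply(observations, function(o) o$image_points)
  resid_fn <- function(p) {
    intr <- camera_intrinsics(fx = p[1], fy = p[2],
                              cx = min(max(p[3], 0), width - 1e-6),
                              cy = min(max(p[4], 0), height - 1e-6),
                              k1 = if (nd) p[5] else 0,
                              k2 = if (nd) p[6] else 0,
                              k3 = if (nd) p[7] else 0,
                              p1 = if (nd) p[8] else 0,
                              p2 = if (nd) p[9] else 0,
                              width = width, height = height)
    res <- numeric(0)
    for (i in seq_len(nview)) {
      off <- 4L + nd + 6L * (i - 1L)
      pose <- unpack_pose(p[off + 1:6])
      proj <- tryCatch(project_points(intr, pose, board$corner_points),
                       error = function(e) NULL)
      if (is.null(proj)) return(rep(1e6, 2L * nrow(xy) * nview))
      res <- c(res, as.numeric(proj - obs_mat[[i]]))
    }
    res
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-12))
  p <- fit$par
  intr <- camera_intrinsics(fx = p[1], fy = p[2], cx = p[3], cy = p[4],
                            k1 = if (nd) p[5] else 0,
                            k2 = if (nd) p[6] else 0,
                            k3 = if (nd) p[7] else 0,
                            p1 = if (nd) p[8] else 0,
                            p2 = if (nd) p[9] else 0,
                            width = width, height = height)
  poses <- lapply(seq_len(nview), function(i) {
    off <- 4L + nd + 6L * (i - 1L)
    unpack_pose(p[off + 1:6])
  })
  per_view <- vapply(seq_len(nview), function(i) {
    reprojection_error_px(intr, poses[[i]], board, observations[[i]])[["mean"]]
  }, numeric(1))
  errs <- unlist(lapply(seq_len(nview), function(i) {
    proj <- project_points(intr, poses[[i]], board$corner_points)
    sqrt(rowSums((proj - obs_mat[[i]])^2))
  }))
  list(intrinsics = intr, poses = poses,
       mean_reprojection_px = mean(errs), per_view_error_px = per_view)
}

#' Estimate the board pose from one observation
#'
#' Recovers the board-to-camera extrinsic pose (the transform expressing board
#' coordinates in the camera optical frame — the checkerboard pose V of the
#' co-registration chain) from a calibrated camera and one full corner
#' observation: observed corners are undistorted, the plane homography is
#' decomposed for an initial pose, and the pose is refined by
#' Levenberg-Marquardt minimisation of the reprojection error.
#'
#' @param intr calibrated `camera_intrinsics`.
#' @param board `checkerboard`.
#' @param obs `corner_observation` covering all corners.
#' @return A board-to-camera `rigid_transform`.
#' @export
estimate_board_pose <- function(intr, board, obs) {
  stopifnot(nrow(obs$image_points) == nrow(board$corner_points))
  norm_xy <- cbind((obs$image_points[, 1] - intr$cx) / intr$fx,
                   (obs$image_points[, 2] - intr$cy) / intr$fy)
  und <- undistort_normalized(norm_xy, intr)
  H <- estimate_homography(board$corner_points[, 1:2, drop = FALSE], und)
  pose0 <- pose_from_homography(H, diag(3))
  resid_fn <- function(p) {
    pose <- unpack_pose(p)
    proj <- tryCatch(project_points(intr, pose, board$corner_points),
                     error = function(e) NULL)
    if (is.null(proj)) return(rep(1e6, 2L * nrow(obs$image_points)))
    as.numeric(proj - obs$image_points)
  }
  fit <- minpack.lm::nls.lm(par = pack_pose(pose0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-13))
  pose <- unpack_pose(fit$par)
  # board normal vs viewing direction: warn when nearly edge-on
  n_cam <- pose$R[, 3]
  view <- pose$t / sqrt(sum(pose$t^2))
  ang <- acos(min(1, abs(sum(n_cam * view)))) * 180 / pi
  if (ang > 85) warning("unstable-pose: board nearly edge-on (tilt > 85 deg)")
  pose
}

#' Reprojection error of an observation against a projected board
#'
#' @param intr `camera_intrinsics`.
#' @param pose board-to-camera `rigid_transform`.
#' @param board `checkerboard`.
#' @param obs `corner_observation`.
#' @return Named numeric vector `c(mean = , sd = )` of per-corner Euclidean
#'   pixel errors (sd is 0 for a single corner).
#' @export
reprojection_error_px <- function(intr, pose, board, obs) {
  proj <- project_points(intr, pose, board$corner_points)
  d <- sqrt(rowSums((proj - obs$image_points)^2))
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0)
}

# --- file interfaces ---------------------------------------------------------

#' Read and write camera intrinsics as YAML
#' @param intr `camera_intrinsics`.
#' @param path file path.
#' @return `read_intrinsics` returns a `camera_intrinsics`.
#' @export
write_intrinsics <- function(intr, path) {
  yaml::write_yaml(unclass(intr), path, precision = 17)
  invisible(path)
}

#' @rdname write_intrinsics
#' @export
read_intrinsics <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(camera_intrinsics, v[c("fx", "fy", "cx", "cy", "k1", "k2", "k3",
                                 "p1", "p2", "width", "height")])
}

#' Read and write corner observations as CSV
#'
#' Schema: `capture_id, corner_index, u_px, v_px`; corner_index is 1-based
#' row-major board order.
#'
#' @param observations list of `corner_observation`.
#' @param path file path.
#' @return `read_corners` returns a list of `corner_observation`.
#' @export
write_corners <- function(observations, path) {
  rows <- do.call(rbind, lapply(observations, function(o) {
    data.frame(capture_id = o$capture_id,
               corner_index = seq_len(nrow(o$image_points)),
               u_px = o$image_points[, 1], v_px = o$image_points[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corners
#' @export
read_corners <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("capture_id", "corner_index", "u_px", "v_px")
  if (!all(need %in% names(df))) {
    stop("format error: corners file missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$capture_id), function(g) {
    g <- g[order(g$corner_index), ]
    corner_observation(cbind(g$u_px, g$v_px), capture_id = g$capture_id[1])
  })
}
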