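#' Rigid-body transforms in SE(3)
#'
#' A `rigid_transform` holds a proper rotation matrix and a translation vector
#' and represents an element of SE(3). The convention used throughout the
#' package is column-vector, point-mapping: the transform `T_{B<-A}` maps a
#' point expressed in frame A to its coordinates in frame B via
#' `p_B = R %*% p_A + t`. All translations are in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  tf <- structure(list(R = rotation, t = translation), class = "rigid_transform")
  validate_transform(tf)
  tf
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(rotation_angle_deg(x$R), error = function(e) NA_real_)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

validate_transform <- function(tf) {
  if (!is.list(tf) || is.null(tf$R) || is.null(tf$t)) {
    stop("invalid-transform: expected a rigid_transform with R and t")
  }
  if (!all(is.finite(tf$R)) || !all(is.finite(tf$t))) {
    stop("invalid-transform: non-finite entries")
  }
  err <- max(abs(crossprod(tf$R) - diag(3)))
  if (err > 1e-9) {
    stop(sprintf("invalid-transform: rotation not orthonormal (deviation %.3g)", err))
  }
  if (det(tf$R) < 0) {
    stop("invalid-transform: improper rotation (reflection)")
  }
  invisible(tf)
}

#' Is an object a valid rigid transform?
#' @param x object to test.
#' @return Logical scalar.
#' @export
is_rigid_transform <- function(x) {
  inherits(x, "rigid_transform") &&
    !inherits(tryCatch(validate_transform(x), error = function(e) e), "error")
}

# Project a near-rotation back onto SO(3) via SVD (polar decomposition).
orthonormalize_rotation <- function(R) {
  s <- svd(R)
  D <- diag(3)
  D[3, 3] <- sign(det(s$u %*% t(s$v)))
  s$u %*% D %*% t(s$v)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` maps a point `p` as `a(b(p))`; frames chain as
#' `T_{C<-A} = compose(T_{C<-B}, T_{B<-A})`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(a, b) {
  validate_transform(a); validate_transform(b)
  R <- a$R %*% b$R
  if (max(abs(crossprod(R) - diag(3))) > 1e-12) R <- orthonormalize_rotation(R)
  rigid_transform(R, as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert <- function(t) {
  validate_transform(t)
  Rt <- t(t$R)
  rigid_transform(Rt, as.numeric(-Rt %*% t$t))
}

#' Apply a rigid transform to points
#' @param t a `rigid_transform`.
#' @param points N x 3 numeric matrix (mm); a length-3 vector is accepted.
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(t, points) {
  validate_transform(t)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (!all(is.finite(points))) stop("data error: non-finite point coordinates")
  sweep(points %*% t(t$R), 2L, t$t, "+")
}

#' Least-squares rigid fit between corresponding point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimising
#' `sum ||R s_i + t - t_i||^2` over index-aligned correspondences. Reflection
#' solutions are rejected by the usual determinant sign correction.
#'
#' @param source,target N x 3 matrices (mm), rows corresponding.
#' @return The fitted `rigid_transform` mapping source onto target.
#' @export
rigid_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, ncol(target) == 3L, nrow(source) == nrow(target))
  n <- nrow(source)
  if (n < 3L) stop("degenerate-configuration: need at least 3 correspondences")
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2L, cs); T_ <- sweep(target, 2L, ct)
  # collinearity check: second singular value of the centred source
  sv <- svd(S, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate-configuration: source points are collinear")
  }
  H <- crossprod(S, T_)
  dec <- svd(H)
  D <- diag(3)
  D[3, 3] <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% D %*% t(dec$u)
  if (max(abs(crossprod(R) - diag(3))) > 1e-12) R <- orthonormalize_rotation(R)
  rigid_transform(R, as.numeric(ct - R %*% cs))
}

# --- quaternion helpers (unit quaternions, scalar-first w,x,y,z) -------------

rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

axis_angle_to_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_to_axis_angle <- function(R) {
  q <- rotation_to_quaternion(R)
  if (q[1] < 0) q <- -q
  th <- 2 * acos(min(1, q[1]))
  s <- sqrt(max(0, 1 - q[1]^2))
  if (s < 1e-12) return(c(0, 0, 0))
  (q[2:4] / s) * th
}

rotation_angle_deg <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Average a set of rigid transforms
#'
#' The translation is the arithmetic mean; the rotation is the chordal mean of
#' the unit quaternions (largest eigenvector of the sum of sign-aligned outer
#' products), which for the small spreads arising between repeat captures at
#' one position agrees with the iterative Karcher mean to well below 0.01
#' degrees.
#'
#' @param transforms non-empty list of `rigid_transform` objects.
#' @return The mean `rigid_transform`.
#' @export
mean_transform <- function(transforms) {
  if (length(transforms) == 0L) stop("argument error: empty transform list")
  lapply(transforms, validate_transform)
  if (length(transforms) == 1L) return(transforms[[1]])
  qs <- t(vapply(transforms, function(tf) rotation_to_quaternion(tf$R),
                 numeric(4)))
  # hemisphere alignment against the first quaternion
  ref <- qs[1, ]
  for (i in seq_len(nrow(qs))) {
    d <- sum(qs[i, ] * ref)
    if (abs(d) < 1e-9) stop("ambiguous-mean: antipodal rotations in set")
    if (d < 0) qs[i, ] <- -qs[i, ]
  }
  A <- crossprod(qs)
  q_mean <- eigen(A, symmetric = TRUE)$vectors[, 1]
  ts <- t(vapply(transforms, function(tf) tf$t, numeric(3)))
  rigid_transform(quaternion_to_rotation(q_mean), colMeans(ts))
}

#' Geodesic rotation distance between two transforms
#'
#' Returns `acos((trace(Ra' Rb) - 1) / 2)` in degrees, clamped to `[0, 180]`.
#'
#' @param a,b `rigid_transform` objects.
#' @return Angle in degrees.
#' @export
rotation_geodesic_deg <- function(a, b) {
  validate_transform(a); validate_transform(b)
  rotation_angle_deg(crossprod(a$R, b$R))
}

#' Rotation about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees.
#' @param translation optional translation (mm).
#' @return A `rigid_transform`.
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), angle_deg,
                          translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
  rigid_transform(R, translation)
}

#' Draw a random rigid transform
#'
#' Rotation uniform on SO(3) via random unit quaternion; translation uniform
#' in a cube of half-width `trans_range_mm`. Uses the current RNG state.
#'
#' @param trans_range_mm half-width of the translation cube (mm).
#' @return A `rigid_transform`.
#' @export
random_transform <- function(trans_range_mm = 100) {
  q <- stats::rnorm(4)
  rigid_transform(quaternion_to_rotation(q / sqrt(sum(q^2))),
                  stats::runif(3, -trans_range_mm, trans_range_mm))
}

# --- pose table IO -----------------------------------------------------------

#' Read and write tracked pose tables
#'
#' The CSV schema has one row per tracked rigid-body pose:
#' `frame_id, body_id, qw, qx, qy, qz, tx_mm, ty_mm, tz_mm` (unit quaternion,
#' scalar first). The JSON form stores each pose as a row-major 4x4 matrix.
#' The CSV round-trips the quaternion form bit-exactly (full double precision).
#'
#' @param path file path.
#' @param poses data frame with columns `frame_id`, `body_id`, `pose`
#'   (list-column of `rigid_transform`).
#' @return `read_pose_table` returns such a data frame.
#' @export
read_pose_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "body_id", "qw", "qx", "qy", "qz",
            "tx_mm", "ty_mm", "tz_mm")
  if (!all(need %in% names(df))) {
    stop("format error: pose table missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$frame_id <- as.character(df$frame_id)
  df$body_id <- as.character(df$body_id)
  poses <- lapply(seq_len(nrow(df)), function(i) {
    q <- c(df$qw[i], df$qx[i], df$qy[i], df$qz[i])
    rigid_transform(quaternion_to_rotation(q),
                    c(df$tx_mm[i], df$ty_mm[i], df$tz_mm[i]))
  })
  out <- df[, c("frame_id", "body_id", "qw", "qx", "qy", "qz",
                "tx_mm", "ty_mm", "tz_mm")]
  out$pose <- poses
  out
}

#' @rdname read_pose_table
#' @export
write_pose_table <- function(poses, path) {
  stopifnot(is.data.frame(poses), all(c("frame_id", "body_id", "pose") %in%
                                        names(poses)))
  has_q <- all(c("qw", "qx", "qy", "qz") %in% names(poses))
  rows <- lapply(seq_len(nrow(poses)), function(i) {
    tf <- poses$pose[[i]]
    validate_transform(tf)
    # reuse stored quaternions when present so read -> write is bit-exact
    q <- if (has_q) c(poses$qw[i], poses$qx[i], poses$qy[i], poses$qz[i])
         else rotation_to_quaternion(tf$R)
    if (q[1] < 0) q <- -q
    data.frame(frame_id = poses$frame_id[i], body_id = poses$body_id[i],
               qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               tx_mm = tf$t[1], ty_mm = tf$t[2], tz_mm = tf$t[3])
  })
  df <- do.call(rbind, rows)
  # full precision so the quaternion form round-trips bit-exactly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  for (i in seq_len(nrow(df))) {
    writeLines(paste(c(df$frame_id[i], df$body_id[i],
                       sprintf("%.17g", as.numeric(df[i, 3:9]))),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname read_pose_table
#' @export
write_pose_json <- function(poses, path) {
  obj <- lapply(seq_len(nrow(poses)), function(i) {
    tf <- poses$pose[[i]]
    M <- rbind(cbind(tf$R, tf$t), c(0, 0, 0, 1))
    list(frame_id = poses$frame_id[i], body_id = poses$body_id[i],
         matrix_rowmajor = as.numeric(t(M)))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_pose_table
#' @export
read_pose_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  poses <- lapply(obj, function(e) {
    M <- matrix(as.numeric(unlist(e$matrix_rowmajor)), 4, 4, byrow = TRUE)
    rigid_transform(orthonormalize_rotation(M[1:3, 1:3]), M[1:3, 4])
  })
  data.frame(frame_id = vapply(obj, function(e) as.character(e$frame_id), ""),
             body_id = vapply(obj, function(e) as.character(e$body_id), "")) ->
    out
  out$pose <- poses
  out
}
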