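#' One tracked calibration capture
#'
#' Bundles the tracked poses and image-derived board pose for one capture of
#' the hand-eye co-registration session:
#' * `m_camera` — pose of the camera's tracked rigid body in the tracking
#'   frame (camera-body to tracking),
#' * `m_board` — pose of the checkerboard's tracked rigid body in the tracking
#'   frame (board-body to tracking),
#' * `v` — board-to-optical extrinsic pose from [estimate_board_pose()],
#' * `corners` — optional `corner_observation` for reprojection validation.
#'
#' @param m_camera,m_board,v `rigid_transform` objects.
#' @param corners optional `corner_observation`.
#' @param capture_id identifier.
#' @return An object of class `tracked_capture`.
#' @export
tracked_capture <- function(m_camera, m_board, v, corners = NULL,
                            capture_id = "capture") {
  validate_transform(m_camera); validate_transform(m_board)
  validate_transform(v)
  structure(list(m_camera = m_camera, m_board = m_board, v = v,
                 corners = corners, capture_id = capture_id),
            class = "tracked_capture")
}

#' Relative transform between the two tracked rigid bodies
#'
#' `M = m_board^-1 o m_camera`: re-expresses camera-rigid-body coordinates in
#' the board-rigid-body frame. This is the M of the calibration chain
#' `G = (M o E o V)^-1`.
#'
#' @param capture a `tracked_capture`.
#' @return A `rigid_transform`.
#' @export
relative_m <- function(capture) {
  compose(invert(capture$m_board), capture$m_camera)
}

# board corners mapped into the board-rigid-body frame through the chain
# M o E o V for one capture; constant across captures when E is correct.
chain_points <- function(e_candidate, capture, board) {
  tf <- compose(relative_m(capture), compose(e_candidate, capture$v))
  transform_points(tf, board$corner_points)
}

#' Spread of chained checkerboard points across captures
#'
#' For a candidate mount transform E, every board corner is mapped through the
#' per-capture chain `M_i o E o V_i` into the board-rigid-body frame, where it
#' should land at the same physical location for every capture. The objective
#' is the mean over corners of the per-corner 3D standard deviation (root of
#' the summed coordinate variances) across captures — zero only for perfectly
#' consistent noise-free captures.
#'
#' @param e_candidate `rigid_transform`, optical-centre to camera-rigid-body.
#' @param captures list of `tracked_capture` (>= 2).
#' @param board `checkerboard`.
#' @return Objective value (mm).
#' @export
spread_objective <- function(e_candidate, captures, board) {
  if (length(captures) < 2L) {
    stop("underdetermined: need at least 2 captures")
  }
  pre <- precompute_chain(captures, board)
  spread_objective_fast(e_candidate$R, e_candidate$t, pre)
}

# constants of the spread objective: M_i and the V_i-mapped corners
precompute_chain <- function(captures, board) {
  list(M = lapply(captures, relative_m),
       Q = lapply(captures, function(cp)
         transform_points(cp$v, board$corner_points)))
}

spread_objective_fast <- function(ER, Et, pre) {
  k <- length(pre$M)
  n <- nrow(pre$Q[[1]])
  s1 <- matrix(0, n, 3L); s2 <- matrix(0, n, 3L)
  tER <- t(ER)
  for (i in seq_len(k)) {
    M <- pre$M[[i]]
    p <- (pre$Q[[i]] %*% tER) %*% t(M$R)
    cc <- as.numeric(M$R %*% Et + M$t)
    p[, 1] <- p[, 1] + cc[1]; p[, 2] <- p[, 2] + cc[2]; p[, 3] <- p[, 3] + cc[3]
    s1 <- s1 + p
    s2 <- s2 + p * p
  }
  v <- (s2 - s1 * s1 / k) / (k - 1)   # per-corner per-coordinate sample var
  mean(sqrt(pmax(0, rowSums(v))))
}

# Closed-form hand-eye initialisation (Tsai-Lenz). The consistency
# M_i E V_i = M_j E V_j rearranges to A_ij E = E B_ij with
# A_ij = M_j^-1 M_i and B_ij = V_j V_i^-1 — the classic AX = XB problem.
# Rotation from the axis-angle linear system, translation from stacked
# least squares; used only as the optimiser's starting point.
init_eg_closed_form <- function(captures) {
  k <- length(captures)
  Ms <- lapply(captures, relative_m)
  pairs <- list()
  for (i in seq_len(k - 1L)) pairs[[i]] <- c(i, i + 1L)
  if (k >= 3L) pairs[[length(pairs) + 1L]] <- c(1L, k)
  Arows <- list(); brows <- list()
  AA <- list(); BB <- list()
  for (pr in pairs) {
    A <- compose(invert(Ms[[pr[2]]]), Ms[[pr[1]]])
    B <- compose(captures[[pr[2]]]$v, invert(captures[[pr[1]]]$v))
    a <- rotation_to_axis_angle(A$R); b <- rotation_to_axis_angle(B$R)
    if (sqrt(sum(a^2)) < 1e-6) next
    pa <- 2 * sin(sqrt(sum(a^2)) / 2) * a / sqrt(sum(a^2))
    pb <- 2 * sin(sqrt(sum(b^2)) / 2) * b / sqrt(sum(b^2))
    s <- pa + pb
    S <- matrix(c(0, -s[3], s[2], s[3], 0, -s[1], -s[2], s[1], 0), 3,
                byrow = TRUE)
    Arows[[length(Arows) + 1L]] <- S
    brows[[length(brows) + 1L]] <- pb - pa
    AA[[length(AA) + 1L]] <- A
    BB[[length(BB) + 1L]] <- B
  }
  if (length(Arows) < 2L) return(rigid_transform())
  S <- do.call(rbind, Arows); y <- unlist(brows)
  x <- tryCatch(qr.solve(S, y), error = function(e) NULL)
  if (is.null(x)) return(rigid_transform())
  x <- 2 * x / sqrt(1 + sum(x^2))
  w <- sqrt(pmax(0, 4 - sum(x^2)))
  R <- orthonormalize_rotation(
    (1 - sum(x^2) / 2) * diag(3) +
      0.5 * (outer(x, x) + w * matrix(c(0, -x[3], x[2], x[3], 0, -x[1],
                                        -x[2], x[1], 0), 3, byrow = TRUE)))
  L <- do.call(rbind, lapply(AA, function(A) A$R - diag(3)))
  r <- unlist(Map(function(A, B) as.numeric(R %*% B$t - A$t), AA, BB))
  t_ <- tryCatch(qr.solve(L, r), error = function(e) c(0, 0, 0))
  rigid_transform(R, t_)
}

#' Solve the hand-eye co-registration
#'
#' Simultaneously estimates the camera mount transform E (optical centre to
#' camera rigid body) and the board mount transform G from tracked captures by
#' minimising [spread_objective()] over the 6 degrees of freedom of E
#' (axis-angle rotation + translation, L-BFGS-B). G is a deterministic
#' function of E given a capture (`G = (M o E o V)^-1`), so it is eliminated
#' from the search and recovered post hoc as the [mean_transform()] of the
#' per-capture values — equivalent to a joint 12-d.o.f. search at the optimum,
#' at half the dimension.
#'
#' @param captures list of `tracked_capture` (>= 3 recommended).
#' @param board `checkerboard`.
#' @param init optional initial E (`rigid_transform`); by default a
#'   closed-form AX = XB hand-eye estimate (Tsai-Lenz) computed from capture
#'   pairs, which places the start inside the global basin.
#' @param maxit iteration cap for the optimiser.
#' @return An object of class `coregistration_result` with elements `e`, `g`,
#'   `objective_value` (mm), `per_capture_residual_mm`, `n_captures`,
#'   `converged`.
#' @export
solve_eg <- function(captures, board, init = NULL, maxit = 500L) {
  if (length(captures) < 2L) stop("underdetermined: need at least 2 captures")
  if (length(captures) < 3L) {
    warning("conditioning: fewer than 3 captures; solution may be weak")
  }
  rot_div <- max(vapply(captures, function(cp)
    rotation_geodesic_deg(captures[[1]]$m_camera, cp$m_camera), numeric(1)))
  if (rot_div < 10) {
    warning("conditioning: camera pose rotation diversity below 10 degrees")
  }
  p0 <- pack_pose(if (is.null(init)) init_eg_closed_form(captures) else init)
  pre <- precompute_chain(captures, board)
  fn <- function(p) spread_objective_fast(axis_angle_to_rotation(p[1:3]),
                                          p[4:6], pre)
  opt <- stats::optim(p0, fn, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10, pgtol = 1e-12,
                                     parscale = c(0.02, 0.02, 0.02, 5, 5, 5),
                                     ndeps = rep(1e-7, 6)))
  e <- unpack_pose(opt$par)
  per_capture_g <- lapply(captures, function(cp) {
    invert(compose(relative_m(cp), compose(e, cp$v)))
  })
  g <- mean_transform(per_capture_g)
  # residual: distance of each capture's implied board points to the mean
  pts <- lapply(captures, chain_points, e_candidate = e, board = board)
  mean_pts <- Reduce(`+`, pts) / length(pts)
  resid <- vapply(pts, function(p) mean(sqrt(rowSums((p - mean_pts)^2))),
                  numeric(1))
  structure(list(e = e, g = g, objective_value = opt$value,
                 per_capture_residual_mm = resid,
                 n_captures = length(captures),
                 converged = opt$convergence == 0L),
            class = "coregistration_result")
}

#' @export
print.coregistration_result <- function(x, ...) {
  cat(sprintf("<coregistration_result> %d captures, objective %.5f mm%s\n",
              x$n_captures, x$objective_value,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Reprojection validation of a co-registration
#'
#' Maps the virtual checkerboard corners through the estimated E/G chain and
#' the tracked poses into the optical frame
#' (`E^-1 o m_camera^-1 o m_board o G^-1`), projects them with the camera
#' intrinsics and compares against the observed corners — the pixel-domain
#' check of calibration quality. With ground-truth E, G on noise-free captures
#' the chain collapses to V and the error is zero.
#'
#' @param result `coregistration_result`.
#' @param captures list of `tracked_capture` carrying corner observations.
#' @param intr `camera_intrinsics`.
#' @param board `checkerboard`.
#' @return Named numeric vector `c(mean = , sd = )` in px over all corners and
#'   captures.
#' @export
coreg_projection_error_px <- function(result, captures, intr, board) {
  errs <- unlist(lapply(captures, function(cp) {
    if (is.null(cp$corners)) {
      stop("data error: capture lacks corner observations")
    }
    chain <- compose(invert(result$e),
                     compose(invert(cp$m_camera),
                             compose(cp$m_board, invert(result$g))))
    proj <- project_points(intr, chain, board$corner_points)
    sqrt(rowSums((proj - cp$corners$image_points)^2))
  }))
  c(mean = mean(errs), sd = stats::sd(errs))
}

#' Write and read a co-registration result as JSON
#' @param result `coregistration_result`.
#' @param path file path.
#' @return `read_coreg_json` returns a `coregistration_result`.
#' @export
write_coreg_json <- function(result, path) {
  tf_json <- function(tf) {
    q <- rotation_to_quaternion(tf$R)
    if (q[1] < 0) q <- -q
    list(quaternion_wxyz = q, translation_mm = tf$t)
  }
  jsonlite::write_json(list(
    e = tf_json(result$e), g = tf_json(result$g),
    objective_mm = result$objective_value,
    per_capture_residual_mm = result$per_capture_residual_mm,
    n_captures = result$n_captures, converged = result$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coreg_json
#' @export
read_coreg_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- function(e) rigid_transform(quaternion_to_rotation(e$quaternion_wxyz),
                                    e$translation_mm)
  structure(list(e = tf(v$e), g = tf(v$g), objective_value = v$objective_mm,
                 per_capture_residual_mm = v$per_capture_residual_mm,
                 n_captures = v$n_captures, converged = v$converged),
            class = "coregistration_result")
}
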