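#' Nearest-neighbour lookup between point clouds
#'
#' For every query point, the index (1-based) and Euclidean distance of the
#' closest reference point. The default engine is a kd-tree (built per call);
#' `method = "brute"` runs the exhaustive scan. Both agree exactly, including
#' tie-breaking toward the lowest reference index.
#'
#' @param query N x 3 matrix (mm).
#' @param reference M x 3 matrix (mm), non-empty.
#' @param method "kdtree" or "brute".
#' @return List with `index` (integer N) and `distance` (numeric N, mm).
#' @export
nearest_neighbors <- function(query, reference, method = c("kdtree", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L)
  if (is.null(dim(reference))) reference <- matrix(reference, ncol = 3L)
  query <- as.matrix(query); reference <- as.matrix(reference)
  if (nrow(reference) == 0L) stop("argument error: empty reference cloud")
  storage.mode(query) <- "double"; storage.mode(reference) <- "double"
  if (method == "kdtree") .cpp_nn_kdtree(query, reference)
  else .cpp_nn_brute(query, reference)
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in each cubic voxel by their centroid.
#'
#' @param cloud N x 3 matrix (mm).
#' @param voxel_mm voxel edge length (mm).
#' @return Downsampled matrix.
#' @export
voxel_downsample <- function(cloud, voxel_mm = 5) {
  stopifnot(voxel_mm > 0)
  cloud <- as.matrix(cloud)
  key <- paste(floor(cloud[, 1] / voxel_mm), floor(cloud[, 2] / voxel_mm),
               floor(cloud[, 3] / voxel_mm))
  g <- split(seq_len(nrow(cloud)), key)
  out <- t(vapply(g, function(ix) colMeans(cloud[ix, , drop = FALSE]),
                  numeric(3)))
  unname(out)
}

#' Surface registration result
#'
#' @param transform source-to-target `rigid_transform`.
#' @param overlap_fraction fraction of source points with a target neighbour
#'   within tolerance after alignment.
#' @param inlier_rmse_mm RMSE over the inlier correspondences (mm).
#' @param n_iterations iterations run.
#' @param converged logical.
#' @return An object of class `registration_result`.
#' @export
registration_result <- function(transform, overlap_fraction, inlier_rmse_mm,
                                n_iterations, converged) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, inlier_rmse_mm >= 0)
  structure(list(transform = transform, overlap_fraction = overlap_fraction,
                 inlier_rmse_mm = inlier_rmse_mm, n_iterations = n_iterations,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> rmse %.4f mm, overlap %.3f, %d iterations%s\n",
    x$inlier_rmse_mm, x$overlap_fraction, x$n_iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# principal-axes candidate alignments: centroid match plus the four proper
# sign assignments of the covariance eigenvector frames. One of the four is
# always near the true orientation (up to the eigenvector ordering), which
# guarantees the RANSAC candidate pool contains the right basin.
principal_axes_candidates <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  es <- eigen(stats::cov(source), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(target), symmetric = TRUE)$vectors
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    for (s3 in c(1, -1)) {
      E <- es %*% diag(c(s1, s2, s3))
      R <- et %*% t(E)
      if (det(R) < 0) next
      R <- orthonormalize_rotation(R)
      out[[length(out) + 1L]] <-
        rigid_transform(R, as.numeric(ct - R %*% cs))
    }
  }
  out
}

principal_axes_init <- function(source, target) {
  cands <- principal_axes_candidates(source, target)
  best <- NULL; best_score <- Inf
  sub <- source[seq_len(min(200L, nrow(source))), , drop = FALSE]
  for (tf in cands) {
    sc <- mean(nearest_neighbors(transform_points(tf, sub), target)$distance)
    if (sc < best_score) { best_score <- sc; best <- tf }
  }
  best
}

#' RANSAC global initialisation for surface registration
#'
#' Repeatedly samples a well-spread source triplet, finds target triplets
#' compatible with its pairwise distances (rotation-invariant descriptor),
#' fits a rigid transform to the three pairs and scores it by the number of
#' source inliers within `inlier_tol_mm` of the target. The best-scoring
#' transform is returned; deterministic per seed. If no candidate reaches 3
#' inliers, a centroid + principal-axes alignment is returned as fallback.
#'
#' @param source,target N x 3 / M x 3 matrices (mm), both >= 3 points.
#' @param seed integer seed.
#' @param max_trials RANSAC iterations.
#' @param inlier_tol_mm inlier distance tolerance (mm).
#' @param score_subsample source points used for trial scoring.
#' @return A source-to-target `rigid_transform`.
#' @export
ransac_global_init <- function(source, target, seed = 0L, max_trials = 600L,
                               inlier_tol_mm = 8, score_subsample = 250L) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3L || nrow(target) < 3L) {
    stop("argument error: clouds must contain at least 3 points")
  }
  with_seed(seed, {
    n <- nrow(source); m <- nrow(target)
    sub <- if (n > score_subsample) sample.int(n, score_subsample) else seq_len(n)
    ssub <- source[sub, , drop = FALSE]
    dist_tol <- inlier_tol_mm / 2
    min_sep <- min(40, 0.4 * max(stats::dist(source[
      sample.int(n, min(n, 50L)), , drop = FALSE])))
    # stage 1: cheap candidate generation from distance-compatible triplets
    cands <- list()
    for (trial in seq_len(max_trials)) {
      si <- sample.int(n, 3L)
      s3 <- source[si, , drop = FALSE]
      d12 <- sqrt(sum((s3[1, ] - s3[2, ])^2))
      d13 <- sqrt(sum((s3[1, ] - s3[3, ])^2))
      d23 <- sqrt(sum((s3[2, ] - s3[3, ])^2))
      if (min(d12, d13, d23) < min_sep) next   # compact/collinear triplets
      t1 <- target[sample.int(m, 1L), ]
      dt1 <- sqrt(rowSums(sweep(target, 2L, t1)^2))
      c2 <- which(abs(dt1 - d12) < dist_tol)
      if (!length(c2)) next
      for (rep2 in seq_len(2L)) {
        t2 <- target[c2[sample.int(length(c2), 1L)], ]
        dt2 <- sqrt(rowSums(sweep(target, 2L, t2)^2))
        c3 <- which(abs(dt1 - d13) < dist_tol & abs(dt2 - d23) < dist_tol)
        if (!length(c3)) next
        t3 <- target[c3[sample.int(length(c3), 1L)], ]
        tf <- tryCatch(rigid_fit(s3, rbind(t1, t2, t3)),
                       error = function(e) NULL)
        if (!is.null(tf)) cands[[length(cands) + 1L]] <- tf
      }
    }
    # principal-axes alignments always join the pool: one of the four proper
    # sign assignments lies in the true basin, so the polish stage can never
    # be left without a viable candidate
    pa <- principal_axes_candidates(source, target)
    pa_idx <- length(cands) + seq_along(pa)
    cands <- c(cands, pa)
    # stage 2: batch inlier voting (single spatial index over the target)
    votes <- .cpp_score_candidates(
      ssub, target, lapply(cands, `[[`, "R"),
      do.call(rbind, lapply(cands, `[[`, "t")), inlier_tol_mm)
    # stage 3: polish a diverse set of strong candidates with a short ICP and
    # rescore at a tight tolerance; alignment quality, not raw vote count,
    # decides
    ord <- order(votes, decreasing = TRUE)
    top <- integer(0)
    for (ci in ord) {
      if (votes[ci] < 3L) break
      distinct <- all(vapply(top, function(cj) {
        rotation_geodesic_deg(cands[[ci]], cands[[cj]]) > 10 ||
          sqrt(sum((cands[[ci]]$t - cands[[cj]]$t)^2)) > 20
      }, logical(1)))
      if (distinct) top <- c(top, ci)
      if (length(top) >= 20L) break
    }
    top <- unique(c(top, pa_idx))   # axes candidates are always polished
    polished <- list(); keys <- list()
    for (ci in top) {
      pol <- tryCatch(icp_point_to_point(ssub, target, init = cands[[ci]],
                                         max_iter = 15L,
                                         corr_tol_mm = inlier_tol_mm,
                                         corr_tol_floor_mm = 2,
                                         conv_tol = 1e-7),
                      error = function(e) NULL)
      if (is.null(pol)) next
      d <- nearest_neighbors(transform_points(pol$transform, ssub),
                             target)$distance
      polished[[length(polished) + 1L]] <- pol$transform
      keys[[length(keys) + 1L]] <- c(sum(d < 2.5), -stats::median(d))
    }
    if (!length(polished)) return(cands[[ord[1]]])
    kmat <- do.call(rbind, keys)
    best <- order(kmat[, 1], kmat[, 2], decreasing = TRUE)[1]
    polished[[best]]
  })
}

#' Point-to-point iterative closest point
#'
#' Alternates nearest-neighbour correspondence (with rejection beyond the
#' current tolerance) and closed-form rigid least-squares fitting. The
#' rejection tolerance starts at `corr_tol_mm` and anneals by x0.5 every
#' `anneal_every` iterations down to `corr_tol_floor_mm`. Within every
#' iteration the least-squares step never increases the RMSE of its own
#' correspondence set (the ICP descent guarantee); the per-iteration history
#' (tolerance, pair count, RMSE before/after the fit) is attached to the
#' result for inspection. Convergence is declared when the tolerance has
#' reached its floor and the RMSE improvement falls below `conv_tol`.
#'
#' @param source,target point clouds (N x 3, M x 3, mm).
#' @param init initial source-to-target `rigid_transform`.
#' @param max_iter iteration cap.
#' @param corr_tol_mm initial correspondence rejection tolerance (mm).
#' @param corr_tol_floor_mm annealing floor (mm).
#' @param anneal_every iterations between tolerance halvings.
#' @param conv_tol stop when the RMSE improvement falls below this (mm).
#' @return A `registration_result` with a `history` attribute (one row per
#'   iteration: `tol_mm`, `n_pairs`, `rmse_before_mm`, `rmse_after_mm`).
#' @export
icp_point_to_point <- function(source, target, init = rigid_transform(),
                               max_iter = 100L, corr_tol_mm = 10,
                               corr_tol_floor_mm = 2, anneal_every = 15L,
                               conv_tol = 1e-12) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0L || nrow(target) == 0L) {
    stop("argument error: empty cloud")
  }
  validate_transform(init)
  tf <- init
  prev_rmse <- Inf
  it_done <- 0L
  converged <- FALSE
  hist <- matrix(NA_real_, max_iter, 4L,
                 dimnames = list(NULL, c("tol_mm", "n_pairs",
                                         "rmse_before_mm", "rmse_after_mm")))
  for (it in seq_len(max_iter)) {
    tol <- max(corr_tol_floor_mm,
               corr_tol_mm * 0.5^((it - 1L) %/% anneal_every))
    at_floor <- tol <= corr_tol_floor_mm ||
      corr_tol_mm * 0.5^(it %/% anneal_every) <= corr_tol_floor_mm
    moved <- transform_points(tf, source)
    nn <- nearest_neighbors(moved, target)
    keep <- nn$distance <= tol
    if (!any(keep)) {
      stop(sprintf("divergence error: all correspondences rejected at iteration %d", it))
    }
    pairs_s <- source[keep, , drop = FALSE]
    pairs_t <- target[nn$index[keep], , drop = FALSE]
    rmse_before <- sqrt(mean(nn$distance[keep]^2))
    tf_new <- tryCatch(rigid_fit(pairs_s, pairs_t), error = function(e) tf)
    moved_new <- transform_points(tf_new, pairs_s)
    rmse <- sqrt(mean(rowSums((moved_new - pairs_t)^2)))
    it_done <- it
    hist[it, ] <- c(tol, sum(keep), rmse_before, rmse)
    tf <- tf_new
    if (at_floor && is.finite(prev_rmse) &&
        abs(prev_rmse - rmse) < conv_tol) {
      converged <- TRUE
      break
    }
    prev_rmse <- rmse
  }
  final_tol <- max(corr_tol_floor_mm,
                   corr_tol_mm * 0.5^((it_done - 1L) %/% anneal_every))
  nn_final <- nearest_neighbors(transform_points(tf, source), target)
  keep <- nn_final$distance <= final_tol
  res <- registration_result(
    transform = tf,
    overlap_fraction = mean(keep),
    inlier_rmse_mm = if (any(keep)) sqrt(mean(nn_final$distance[keep]^2)) else Inf,
    n_iterations = it_done, converged = converged)
  attr(res, "history") <- hist[seq_len(it_done), , drop = FALSE]
  res
}

#' Register a captured face cloud to the MR-derived face
#'
#' The full markerless-registration step: both clouds are voxel-downsampled
#' (default 5 mm), RANSAC provides a global initial alignment on the
#' downsampled clouds, and point-to-point ICP refines it at full resolution.
#' The returned transform maps camera-frame coordinates into the patient
#' (MR) frame; the overlap fraction is evaluated at `overlap_tol_mm` on the
#' full-resolution aligned clouds.
#'
#' @param face_cloud camera-frame face capture (N x 3 mm, >= 100 points).
#' @param mr_face patient-frame reference face cloud (M x 3 mm).
#' @param seed integer seed for the RANSAC stage.
#' @param voxel_mm downsampling voxel (mm).
#' @param overlap_tol_mm distance tolerance for the reported overlap (mm).
#' @param ... passed to [icp_point_to_point()].
#' @return A `registration_result` (camera-to-patient).
#' @export
register_face <- function(face_cloud, mr_face, seed = 0L, voxel_mm = 5,
                          overlap_tol_mm = 5, ...) {
  face_cloud <- as.matrix(face_cloud); mr_face <- as.matrix(mr_face)
  if (nrow(face_cloud) < 100L || nrow(mr_face) < 100L) {
    stop("argument error: need at least 100 points per cloud")
  }
  src_ds <- voxel_downsample(face_cloud, voxel_mm)
  # correspondence search runs on the downsampled source against the full
  # target so candidate scoring is not limited by voxel-centroid error
  init <- ransac_global_init(src_ds, mr_face, seed = seed)
  # coarse-to-fine: cheap iterations on the downsampled source close most of
  # the remaining misalignment before the full-resolution refinement
  coarse <- icp_point_to_point(src_ds, mr_face, init = init, max_iter = 150L)
  res <- icp_point_to_point(face_cloud, mr_face, init = coarse$transform, ...)
  nn <- nearest_neighbors(transform_points(res$transform, face_cloud), mr_face)
  registration_result(res$transform,
                      overlap_fraction = mean(nn$distance <= overlap_tol_mm),
                      inlier_rmse_mm = res$inlier_rmse_mm,
                      n_iterations = res$n_iterations,
                      converged = res$converged)
}

#' Carry a camera-frame registration into the tracking frame
#'
#' Combines the surface-registration result (camera optical frame to patient
#' frame) with the tracked camera-body pose and the hand-eye mount E to give
#' the patient-to-tracking transform:
#' `T_track<-patient = m_camera o E o inverse(registration)`.
#'
#' @param reg `registration_result` (camera-to-patient) or a
#'   `rigid_transform`.
#' @param m_camera tracked camera-body pose (`rigid_transform`).
#' @param e hand-eye mount transform E (optical to camera body).
#' @return Patient-to-tracking `rigid_transform`.
#' @export
chain_to_tracking <- function(reg, m_camera, e) {
  tf <- if (inherits(reg, "registration_result")) reg$transform else reg
  compose(m_camera, compose(e, invert(tf)))
}
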