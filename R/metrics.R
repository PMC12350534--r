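#' Overlap fraction between two clouds
#'
#' Fraction of source points whose nearest target neighbour lies within
#' `dist_tol_mm`. Registrations with overlap below 95% are conventionally
#' excluded as failures.
#'
#' @param source,target point clouds (N x 3, M x 3, mm), non-empty.
#' @param dist_tol_mm distance tolerance (mm), positive.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(source, target, dist_tol_mm = 5) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0L || nrow(target) == 0L) {
    stop("argument error: empty cloud")
  }
  stopifnot(dist_tol_mm > 0)
  mean(nearest_neighbors(source, target)$distance <= dist_tol_mm)
}

#' Surface RMSE over overlapping points
#'
#' Root-mean-square of nearest-neighbour distances restricted to source
#' points within `dist_tol_mm` of the target (only overlapping points enter
#' the distance calculation). This one statistic backs both the FRE (face
#' clouds) and the TRE (craniotomy ROI clouds).
#'
#' @inheritParams overlap_fraction
#' @return RMSE (mm).
#' @export
surface_rmse_mm <- function(source, target, dist_tol_mm = 5) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0L || nrow(target) == 0L) {
    stop("argument error: empty cloud")
  }
  d <- nearest_neighbors(source, target)$distance
  keep <- d <= dist_tol_mm
  if (!any(keep)) stop("no-overlap: no source point within tolerance of target")
  sqrt(mean(d[keep]^2))
}

#' Crop a cloud to an axis-aligned box with margin
#'
#' The box is closed: points exactly on a face are included.
#'
#' @param cloud N x 3 matrix (mm).
#' @param box 2 x 3 matrix, rows = min and max corners (mm).
#' @param margin_mm expansion applied to every face (mm).
#' @return The points inside the expanded box.
#' @export
crop_roi <- function(cloud, box, margin_mm = 0) {
  cloud <- as.matrix(cloud); box <- as.matrix(box)
  stopifnot(all(dim(box) == c(2L, 3L)), all(box[1, ] <= box[2, ]))
  lo <- box[1, ] - margin_mm; hi <- box[2, ] + margin_mm
  keep <- cloud[, 1] >= lo[1] & cloud[, 1] <= hi[1] &
    cloud[, 2] >= lo[2] & cloud[, 2] <= hi[2] &
    cloud[, 3] >= lo[3] & cloud[, 3] <= hi[3]
  if (!any(keep)) stop("empty-roi: no points inside the cropped box")
  cloud[keep, , drop = FALSE]
}

#' Landmark (fiducial-marker) registration baseline
#'
#' The manual-registration analogue: of the 8 phantom fiducials, half are
#' used to fit the rigid alignment (their post-fit RMSE is the FRE) and the
#' held-out half evaluates it (their RMSE under the same alignment is the
#' TRE).
#'
#' @param fiducials_measured K x 3 marker centres in the tracking frame (mm).
#' @param fiducials_mr K x 3 corresponding centres in the patient frame (mm).
#' @param use_for_registration indices of the registration subset (>= 3);
#'   default the first half.
#' @return List with `transform` (patient-to-tracking), `fre_mm`, `tre_mm`.
#' @export
landmark_register <- function(fiducials_measured, fiducials_mr,
                              use_for_registration = NULL) {
  fm <- as.matrix(fiducials_measured); fr <- as.matrix(fiducials_mr)
  stopifnot(nrow(fm) == nrow(fr), ncol(fm) == 3L, ncol(fr) == 3L)
  k <- nrow(fm)
  if (is.null(use_for_registration)) use_for_registration <- seq_len(k %/% 2L)
  reg <- sort(unique(as.integer(use_for_registration)))
  if (length(reg) < 3L) stop("argument error: registration subset needs >= 3 markers")
  if (any(reg < 1L | reg > k)) stop("argument error: registration indices out of range")
  hold <- setdiff(seq_len(k), reg)
  if (length(intersect(reg, hold))) stop("argument error: subsets overlap")
  tf <- rigid_fit(fr[reg, , drop = FALSE], fm[reg, , drop = FALSE])
  rms <- function(idx) {
    if (!length(idx)) return(NA_real_)
    moved <- transform_points(tf, fr[idx, , drop = FALSE])
    sqrt(mean(rowSums((moved - fm[idx, , drop = FALSE])^2)))
  }
  list(transform = tf, fre_mm = rms(reg), tre_mm = rms(hold))
}

#' Benchmark configuration
#'
#' Validated container for the evaluation protocol: 10 positions x 5 captures
#' at the registration stage (patient registration + FRE) and the same at the
#' testing stage (TRE on the cropped craniotomy ROI), with the overlap
#' exclusion gate. Unknown keys are rejected rather than silently dropped.
#'
#' @param preset preset name (see [builtin_presets()]) or a
#'   `camera_noise_preset`.
#' @param algorithm registration backend id (currently "icp"; external
#'   backends may be registered, see [registration_backend()]).
#' @param seed integer seed.
#' @param n_positions,n_captures protocol counts per stage.
#' @param overlap_threshold exclusion gate, in (0, 1].
#' @param dist_tol_mm overlap/RMSE distance tolerance (mm).
#' @param voxel_mm registration downsampling voxel (mm).
#' @param roi_margin_mm margin around the craniotomy box (mm).
#' @param point_spacing_mm phantom sampling spacing (mm).
#' @param standoff_registration_mm,standoff_testing_mm camera standoffs (mm).
#' @param tracking_rot_sigma_deg,tracking_trans_sigma_mm tracking jitter.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(preset = "d405", algorithm = "icp", seed = 0L,
                             n_positions = 10L, n_captures = 5L,
                             overlap_threshold = 0.95, dist_tol_mm = 5,
                             voxel_mm = 5, roi_margin_mm = 10,
                             point_spacing_mm = 2.5,
                             standoff_registration_mm = 442,
                             standoff_testing_mm = 454,
                             tracking_rot_sigma_deg = 0.05,
                             tracking_trans_sigma_mm = 0.15) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1, dist_tol_mm > 0,
            voxel_mm > 0, roi_margin_mm >= 0, n_positions >= 1,
            n_captures >= 1, standoff_registration_mm > 0,
            standoff_testing_mm > 0)
  structure(list(preset = preset, algorithm = algorithm, seed = as.integer(seed),
                 n_positions = as.integer(n_positions),
                 n_captures = as.integer(n_captures),
                 overlap_threshold = overlap_threshold,
                 dist_tol_mm = dist_tol_mm, voxel_mm = voxel_mm,
                 roi_margin_mm = roi_margin_mm,
                 point_spacing_mm = point_spacing_mm,
                 standoff_registration_mm = standoff_registration_mm,
                 standoff_testing_mm = standoff_testing_mm,
                 tracking_rot_sigma_deg = tracking_rot_sigma_deg,
                 tracking_trans_sigma_mm = tracking_trans_sigma_mm),
            class = "benchmark_config")
}

#' Read a benchmark configuration from YAML
#'
#' Unknown keys raise a config error so a typo can never silently change a
#' tolerance default.
#'
#' @param path YAML file.
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  v <- yaml::read_yaml(path)
  allowed <- names(formals(benchmark_config))
  bad <- setdiff(names(v), allowed)
  if (length(bad)) {
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  }
  do.call(benchmark_config, v)
}

# backend registry ------------------------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Registration backend adapter
#'
#' A backend is any function `(source, target, seed, ...) ->
#' registration_result`, keyed by an id. "icp" ([register_face()]) is built
#' in; external methods (for example a learned global-registration model) can
#' be plugged in through this seam and benchmarked with the identical
#' protocol. No learned backend is bundled.
#'
#' @param id backend identifier.
#' @param fn backend function; omit to look an existing backend up.
#' @return The backend function, invisibly for registration.
#' @export
registration_backend <- function(id, fn = NULL) {
  if (!is.null(fn)) {
    stopifnot(is.function(fn))
    assign(id, fn, envir = .backends)
    return(invisible(fn))
  }
  if (id == "icp") return(register_face)
  if (!exists(id, envir = .backends)) {
    stop("config error: unknown registration backend '", id, "'")
  }
  get(id, envir = .backends)
}

# sample a camera pose (in the phantom frame) looking at `target_pt` from the
# `direction` hemisphere at the given standoff, with seeded jitter
sample_camera_pose <- function(target_pt, direction, standoff_mm) {
  dir <- direction / sqrt(sum(direction^2))
  side <- stats::rnorm(3, 0, 0.18)
  side <- side - sum(side * dir) * dir
  d <- dir + side; d <- d / sqrt(sum(d^2))
  eye <- target_pt + d * (standoff_mm + stats::rnorm(1, 0, 15))
  look_at_pose(eye, target_pt + stats::rnorm(3, 0, 8))
}

#' Run the full camera-evaluation benchmark
#'
#' Executes the two-stage protocol on the simulator: at the registration
#' stage, `n_positions` camera placements facing the phantom's face, with
#' `n_captures` depth captures each; every capture is registered to the
#' MR-derived face cloud and chained into the tracking frame, a mean
#' transform per position is formed, and the position FRE and overlap are
#' measured. Positions under the overlap threshold are excluded; the
#' patient registration used downstream is the mean transform over the
#' surviving positions. At the testing stage, the same number of placements
#' face the craniotomy; captures are cropped to the craniotomy bounding box
#' (plus margin) in the registered patient frame and the TRE is measured
#' against the MR craniotomy ROI, with the same gate. An all-excluded
#' registration stage yields an all-excluded report, not an error.
#'
#' @param config a `benchmark_config`.
#' @param scene optional pre-built `phantom_scene` (rebuilt from the config
#'   seed when omitted).
#' @return An object of class `evaluation_report`: `per_position` data frame,
#'   `summary` list (FRE/TRE mean and std over non-excluded positions,
#'   `n_excluded`), `provenance` list.
#' @export
run_benchmark <- function(config, scene = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  preset <- if (inherits(config$preset, "camera_noise_preset")) config$preset
            else builtin_presets()[[config$preset]]
  if (is.null(preset)) stop("config error: unknown preset '", config$preset, "'")
  backend <- registration_backend(config$algorithm)
  if (is.null(scene)) {
    scene <- generate_phantom_head(seed = config$seed + 1000L,
                                   point_spacing_mm = config$point_spacing_mm)
  }
  tnoise <- tracking_noise(config$tracking_rot_sigma_deg,
                           config$tracking_trans_sigma_mm)
  mr_face <- scene$surface_points[scene$region_labels == "face", , drop = FALSE]
  # both clouds are cropped with the same expanded craniotomy box, keeping a
  # consistent margin around the region of interest
  mr_roi <- crop_roi(scene$surface_points, scene$craniotomy_box,
                     config$roi_margin_mm)
  face_ctr <- colMeans(mr_face)
  roi_ctr <- colMeans(mr_roi)
  roi_dir <- roi_ctr / sqrt(sum(roi_ctr^2))

  # ground-truth phantom pose in the tracking frame and known camera mount E
  gt <- with_seed(config$seed + 2000L, {
    list(t_w_p = rigid_transform(
           quaternion_to_rotation({q <- stats::rnorm(4); q / sqrt(sum(q^2))}),
           stats::runif(3, -300, 300)),
         e = rigid_transform(axis_angle_to_rotation(stats::rnorm(3, 0, 0.2)),
                             stats::rnorm(3, 0, 40)))
  })

  run_position <- function(phase, pos) {
    base_seed <- config$seed + 10000L * (phase == "testing") + 100L * pos
    standoff <- if (phase == "registration") config$standoff_registration_mm
                else config$standoff_testing_mm
    aim <- if (phase == "registration") face_ctr else roi_ctr
    dir <- if (phase == "registration") c(0, 1, 0.15) else roi_dir
    pose_p_o <- with_seed(base_seed, sample_camera_pose(aim, dir, standoff))
    caps <- vector("list", config$n_captures)
    for (k in seq_len(config$n_captures)) {
      cap_seed <- base_seed + k
      cloud <- simulate_depth_capture(scene, pose_p_o, preset, seed = cap_seed)
      labs <- attr(cloud, "labels")
      m_cam <- with_seed(cap_seed + 50L, simulate_tracked_pose(
        compose(compose(gt$t_w_p, pose_p_o), invert(gt$e)), tnoise))
      caps[[k]] <- list(cloud = cloud, labels = labs, m_cam = m_cam)
    }
    list(pose = pose_p_o, captures = caps)
  }

  per_pos <- list()
  pos_transforms <- vector("list", config$n_positions)
  for (pos in seq_len(config$n_positions)) {
    pd <- run_position("registration", pos)
    est <- list(); pooled_w <- list()
    failed <- FALSE
    for (k in seq_along(pd$captures)) {
      cp <- pd$captures[[k]]
      face_cap <- cp$cloud[cp$labels == "face", , drop = FALSE]
      reg <- tryCatch(
        backend(face_cap, mr_face, seed = config$seed + pos * 10L + k,
                voxel_mm = config$voxel_mm),
        error = function(e) NULL)
      if (is.null(reg)) { failed <- TRUE; next }
      est[[length(est) + 1L]] <- chain_to_tracking(reg, cp$m_cam, gt$e)
      pooled_w[[length(pooled_w) + 1L]] <-
        transform_points(compose(cp$m_cam, gt$e), face_cap)
    }
    if (!length(est)) {
      per_pos[[length(per_pos) + 1L]] <- data.frame(
        phase = "registration", position_id = pos, n_captures = 0L,
        metric_mm = NA_real_, overlap_fraction = 0, excluded = TRUE)
      next
    }
    t_hat <- mean_transform(est)
    pos_transforms[[pos]] <- t_hat
    src <- do.call(rbind, pooled_w)
    tgt <- transform_points(t_hat, mr_face)
    ov <- overlap_fraction(src, tgt, config$dist_tol_mm)
    fre <- tryCatch(surface_rmse_mm(src, tgt, config$dist_tol_mm),
                    error = function(e) NA_real_)
    per_pos[[length(per_pos) + 1L]] <- data.frame(
      phase = "registration", position_id = pos, n_captures = length(est),
      metric_mm = fre, overlap_fraction = ov,
      excluded = ov < config$overlap_threshold)
  }
  reg_rows <- do.call(rbind, per_pos)
  good <- which(!reg_rows$excluded)
  t_reg <- if (length(good)) mean_transform(pos_transforms[good]) else NULL

  test_rows <- list()
  for (pos in seq_len(config$n_positions)) {
    pd <- run_position("testing", pos)
    if (is.null(t_reg)) {
      test_rows[[pos]] <- data.frame(
        phase = "testing", position_id = pos, n_captures = config$n_captures,
        metric_mm = NA_real_, overlap_fraction = 0, excluded = TRUE)
      next
    }
    t_reg_inv <- invert(t_reg)
    src_p <- lapply(pd$captures, function(cp) {
      w <- transform_points(compose(cp$m_cam, gt$e), cp$cloud)
      transform_points(t_reg_inv, w)
    })
    src <- do.call(rbind, src_p)
    src <- tryCatch(crop_roi(src, scene$craniotomy_box, config$roi_margin_mm),
                    error = function(e) NULL)
    if (is.null(src)) {
      test_rows[[pos]] <- data.frame(
        phase = "testing", position_id = pos, n_captures = config$n_captures,
        metric_mm = NA_real_, overlap_fraction = 0, excluded = TRUE)
      next
    }
    ov <- overlap_fraction(src, mr_roi, config$dist_tol_mm)
    tre <- tryCatch(surface_rmse_mm(src, mr_roi, config$dist_tol_mm),
                    error = function(e) NA_real_)
    test_rows[[pos]] <- data.frame(
      phase = "testing", position_id = pos, n_captures = config$n_captures,
      metric_mm = tre, overlap_fraction = ov,
      excluded = ov < config$overlap_threshold)
  }
  rows <- rbind(reg_rows, do.call(rbind, test_rows))
  summ <- function(phase) {
    r <- rows[rows$phase == phase & !rows$excluded, ]
    if (!nrow(r)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(r$metric_mm), sd = stats::sd(r$metric_mm))
  }
  fre_s <- summ("registration"); tre_s <- summ("testing")
  structure(list(
    per_position = rows,
    summary = list(fre_mean_mm = fre_s[["mean"]], fre_std_mm = fre_s[["sd"]],
                   tre_mean_mm = tre_s[["mean"]], tre_std_mm = tre_s[["sd"]],
                   n_excluded = sum(rows$excluded),
                   all_excluded = all(rows$excluded[rows$phase == "registration"])),
    provenance = list(camera_preset = preset$name,
                      algorithm = config$algorithm, seed = config$seed,
                      overlap_threshold = config$overlap_threshold,
                      dist_tol_mm = config$dist_tol_mm,
                      roi_margin_mm = config$roi_margin_mm)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<evaluation_report> %s / %s (seed %d)\n",
              x$provenance$camera_preset, x$provenance$algorithm,
              x$provenance$seed))
  fmt <- function(m, sd_) {
    if (is.na(m)) "Overlay < 95%" else sprintf("%.2f ± %.2f mm", m, sd_)
  }
  cat("  FRE:", fmt(s$fre_mean_mm, s$fre_std_mm),
      " TRE:", fmt(s$tre_mean_mm, s$tre_std_mm),
      sprintf(" (%d excluded)\n", s$n_excluded))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json`, `report.csv` (one row per position plus a summary
#' block in the JSON) into `dir`.
#'
#' @param report `evaluation_report`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_position, file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            provenance = report$provenance,
                            per_position = report$per_position),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Format evaluation reports as a Markdown table
#'
#' One row per report, `mean ± std` per metric, with excluded configurations
#' shown as "Overlay < 95%" — the conventional presentation of a camera
#' comparison.
#'
#' @param reports list of `evaluation_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  fmt <- function(m, s) {
    if (is.na(m)) "Overlay < 95%" else sprintf("%.2f ± %.2f", m, s)
  }
  lines <- c("| Camera | Algorithm | FRE [mm] | TRE [mm] |",
             "|---|---|---|---|")
  for (r in reports) {
    s <- r$summary
    lines <- c(lines, sprintf("| %s | %s | %s | %s |",
                              r$provenance$camera_preset,
                              r$provenance$algorithm,
                              fmt(s$fre_mean_mm, s$fre_std_mm),
                              fmt(s$tre_mean_mm, s$tre_std_mm)))
  }
  lines
}
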