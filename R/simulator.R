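# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# half-width vertical profile of the cranium: closed crown at z = 100 mm
head_profile <- function(z, half_width_mm) {
  g <- sqrt(pmax(0, 1 - (z / 100)^2))
  half_width_mm * g
}

#' Generate the parametric phantom head scene
#'
#' Builds a synthetic patient phantom — the stand-in for the MR-derived head
#' surface — as a closed parametric shape sampled at the requested spacing:
#' an elliptical-cross-section cranium whose width profile yields a bigonial
#' width of 118 mm, a wedge nose of 50 mm length and 35 mm alar base, a
#' circular recessed craniotomy region on the parietal surface, and 8 fiducial
#' marker centres spread over the face and scalp by farthest-point sampling.
#' The phantom frame has x left-right, y toward the face, z up, origin at the
#' head centre.
#'
#' @param seed integer seed; the scene is deterministic per seed.
#' @param point_spacing_mm target sample spacing, in (0.2, 5) mm.
#' @param craniotomy_diameter_mm diameter of the craniotomy patch (mm).
#' @return An object of class `phantom_scene` with `surface_points` (N x 3
#'   mm), `normals` (N x 3 unit), `region_labels` (character in face, scalp,
#'   craniotomy, other), `fine_labels` (adds nose/jaw detail), `fiducials`
#'   (8 x 3 mm), `craniotomy_box` (2 x 3 min/max mm).
#' @export
generate_phantom_head <- function(seed = 1L, point_spacing_mm = 2.5,
                                  craniotomy_diameter_mm = 70) {
  if (point_spacing_mm <= 0.2 || point_spacing_mm >= 5) {
    stop("argument error: point_spacing_mm must lie in (0.2, 5)")
  }
  s <- point_spacing_mm
  with_seed(seed, {
    # cranium: elliptical cross-sections wx(z), wy(z), sampled along a
    # golden-angle spiral so the cloud carries no ring lattice (ring-sampled
    # surfaces alias under small pitch rotations and trap surface
    # registration in spurious minima)
    A_x <- 59 / sqrt(1 - (59 / 100)^2)     # gives half-width 59 mm at z = -59
    z_lo <- -95; z_hi <- 99.5
    z_fine <- seq(z_lo, z_hi, length.out = 1024L)
    perim_f <- function(z) {
      wx <- head_profile(z, A_x); wy <- 1.25 * wx
      pi * (3 * (wx + wy) - sqrt(pmax(0, (3 * wx + wy) * (wx + 3 * wy))))
    }
    per <- perim_f(z_fine)
    cdf <- cumsum(per); cdf <- cdf / cdf[length(cdf)]
    area <- sum(per) * (z_hi - z_lo) / length(z_fine)
    n_cr <- max(100L, round(area / s^2))
    # seeded uniform random sampling: any regular or quasi-regular lattice
    # aliases under rotations of one lattice period and traps ICP
    u <- stats::runif(n_cr)
    z <- stats::approx(cdf, z_fine, xout = u, rule = 2)$y
    th <- stats::runif(n_cr, 0, 2 * pi)
    wx <- head_profile(z, A_x)
    # egg-shaped cross-section: flatter face side, rounder occiput
    wy <- wx * (1.25 - 0.1 * cos(th))
    x <- wx * sin(th); y <- wy * cos(th)     # th = 0 faces +y (the face)
    # implicit-surface gradient of (x/wx)^2 + (y/wy)^2 = 1 with z-varying widths
    dg <- -(z / 100^2) / sqrt(pmax(1e-9, 1 - (z / 100)^2))
    dwx <- A_x * dg; dwy <- 1.25 * A_x * dg
    nn <- cbind(2 * x / wx^2, 2 * y / wy^2,
                -2 * (x^2 / wx^3) * dwx - 2 * (y^2 / wy^3) * dwy)
    nn <- nn / sqrt(rowSums(nn^2))
    P <- cbind(x, y, z); N <- nn
    lab <- rep("other", n_cr)
    lab[y > 0.35 * wy & z > -80 & z < 55] <- "face"
    lab[z >= 55 | (z > 10 & y <= 0.35 * wy)] <- "scalp"

    # nose wedge: ridge at x = 0, z from tip (-28) to bridge (22) -> 50 mm
    z_top <- 22; z_tip <- -28; alar_half <- 17.5; protrusion <- 22
    # low-discrepancy sampling over the (z, x) wedge domain — lattice-free
    # for the same reason as the cranium spiral
    nose_area <- alar_half * (z_top - z_tip)   # triangle, both slopes
    n_nose <- max(30L, round(2 * nose_area / s^2))
    uz <- stats::runif(n_nose)
    ux <- stats::runif(n_nose)
    f_n <- sqrt(uz)                   # density prop. to local width wn
    z_n <- z_top - f_n * (z_top - z_tip)      # f 0 at bridge, 1 at tip/base
    wn <- alar_half * pmax(f_n, 1e-6)
    x_n <- (2 * ux - 1) * wn
    y_n <- head_profile(z_n, A_x) * 1.15 +
      protrusion * f_n * (1 - abs(x_n) / wn)
    NoseP <- cbind(x_n, y_n, z_n)
    slope <- protrusion * f_n / wn
    NoseN <- cbind(sign(x_n) * slope, 1, 0.35)
    NoseN <- NoseN / sqrt(rowSums(NoseN^2))

    # facial relief: eye sockets, brow, cheekbones, mouth, chin — the
    # asymmetric structure a surface registration locks onto
    relief <- rbind(
      # cx, cz, radius_mm, amplitude_mm (+out / -in)
      c(-28, 20, 17, -6.5),   # left eye socket
      c( 28, 20, 17, -6.5),   # right eye socket
      c(  0, 38, 20,  4.5),   # brow/glabella
      c(  0, 62, 26, -4.0),   # flattened forehead
      c(-45, -8, 16,  4.0),   # left cheekbone
      c( 45, -8, 16,  4.0),   # right cheekbone
      c(-55, 25, 14, -3.0),   # left temple hollow
      c( 55, 25, 14, -3.0),   # right temple hollow
      c(  0, -52, 14, -4.0),  # mouth
      c(  0, -75, 13,  5.5))  # chin
    for (ri in seq_len(nrow(relief))) {
      wy_r <- 1.15 * head_profile(relief[ri, 2], A_x)
      ctr_r <- c(relief[ri, 1], wy_r * 0.92, relief[ri, 2])
      dr <- sqrt(rowSums(sweep(P, 2L, ctr_r)^2))
      sel <- dr < relief[ri, 3] & lab == "face"
      amp <- relief[ri, 4] * cos(pi / 2 * dr[sel] / relief[ri, 3])^2
      P[sel, ] <- P[sel, ] + N[sel, ] * amp
    }

    P <- rbind(P, NoseP); N <- rbind(N, NoseN)
    fine_lab <- c(lab, rep("nose", nrow(NoseP)))
    region <- ifelse(fine_lab == "nose", "face", fine_lab)

    # craniotomy: circular patch around a parietal direction, recessed 4 mm
    ctr_dir <- c(0, -0.35, 0.94); ctr_dir <- ctr_dir / sqrt(sum(ctr_dir^2))
    proj_len <- P %*% ctr_dir
    # patch centre: surface point most aligned with the direction
    ctr <- P[which.max(proj_len - 0.001 * rowSums(abs(P))), ]
    d <- sqrt(rowSums(sweep(P, 2L, ctr)^2))
    in_patch <- d < craniotomy_diameter_mm / 2 & fine_lab != "nose"
    depth <- 4 * cos(pi / 2 * d[in_patch] / (craniotomy_diameter_mm / 2))^0.5
    P[in_patch, ] <- P[in_patch, ] - N[in_patch, ] * depth
    region[in_patch] <- "craniotomy"
    fine_lab[in_patch] <- "craniotomy"

    # fiducials: farthest-point sampling over face + scalp
    cand <- which(region %in% c("face", "scalp"))
    fid_idx <- cand[sample.int(length(cand), 1L)]
    while (length(fid_idx) < 8L) {
      dmin <- rep(Inf, length(cand))
      for (fi in fid_idx) {
        dmin <- pmin(dmin, sqrt(rowSums(sweep(P[cand, , drop = FALSE], 2L,
                                              P[fi, ])^2)))
      }
      fid_idx <- c(fid_idx, cand[which.max(dmin)])
    }
    crani_pts <- P[region == "craniotomy", , drop = FALSE]
    box <- rbind(min = apply(crani_pts, 2L, min),
                 max = apply(crani_pts, 2L, max))
    structure(list(surface_points = unname(P), normals = unname(N),
                   region_labels = region, fine_labels = fine_lab,
                   fiducials = unname(P[fid_idx, , drop = FALSE]),
                   craniotomy_box = unname(box),
                   point_spacing_mm = point_spacing_mm, seed = seed),
              class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d points (%.2f mm spacing), regions: %s\n",
              nrow(x$surface_points), x$point_spacing_mm,
              paste(names(table(x$region_labels)), collapse = ", ")))
  invisible(x)
}

#' Anthropometric measurements of a phantom scene
#'
#' `measure_bigonial_width_mm` is twice the maximal lateral extent in the
#' gonion band (z in -61..-59 mm); `measure_nose_length_mm` is the vertical
#' extent of the nose wedge; `measure_alar_base_mm` is the maximal nose width.
#'
#' @param scene a `phantom_scene`.
#' @return Length in mm.
#' @export
measure_bigonial_width_mm <- function(scene) {
  band <- scene$surface_points[, 3] > -61 & scene$surface_points[, 3] < -59
  2 * max(abs(scene$surface_points[band, 1]))
}

#' @rdname measure_bigonial_width_mm
#' @export
measure_nose_length_mm <- function(scene) {
  z <- scene$surface_points[scene$fine_labels == "nose", 3]
  max(z) - min(z) + scene$point_spacing_mm / 2
}

#' @rdname measure_bigonial_width_mm
#' @export
measure_alar_base_mm <- function(scene) {
  x <- scene$surface_points[scene$fine_labels == "nose", 1]
  max(x) - min(x)
}

#' Tracking-system jitter description
#' @param rot_sigma_deg rotational jitter std (degrees).
#' @param trans_sigma_mm translational jitter std per axis (mm).
#' @return An object of class `tracking_noise`.
#' @export
tracking_noise <- function(rot_sigma_deg = 0, trans_sigma_mm = 0) {
  stopifnot(rot_sigma_deg >= 0, trans_sigma_mm >= 0)
  structure(list(rot_sigma_deg = rot_sigma_deg, trans_sigma_mm = trans_sigma_mm),
            class = "tracking_noise")
}

#' Perturb a pose with tracking jitter
#'
#' Rotation is perturbed about a uniformly random axis by an angle drawn from
#' `N(0, rot_sigma_deg)`; translation by isotropic `N(0, trans_sigma_mm)`.
#' Zero noise returns the pose unchanged. Uses the current RNG state unless a
#' seed is given.
#'
#' @param true_pose a `rigid_transform`.
#' @param noise a `tracking_noise`.
#' @param seed optional integer seed.
#' @return A perturbed `rigid_transform`.
#' @export
simulate_tracked_pose <- function(true_pose, noise, seed = NULL) {
  run <- function() {
    if (noise$rot_sigma_deg == 0 && noise$trans_sigma_mm == 0) return(true_pose)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::rnorm(1, 0, noise$rot_sigma_deg) * pi / 180
    dR <- axis_angle_to_rotation(ax * ang)
    dt <- stats::rnorm(3, 0, noise$trans_sigma_mm)
    rigid_transform(dR %*% true_pose$R, true_pose$t + dt)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# camera pose with optical z-axis looking from `eye` toward `target`,
# x right, y down; `up_hint` fixes the roll. Returns camera-to-world.
look_at_pose <- function(eye, target, up_hint = c(0, 0, 1)) {
  z <- target - eye; z <- z / sqrt(sum(z^2))
  x <- pracma_cross(-up_hint, z)
  if (sqrt(sum(x^2)) < 1e-6) x <- pracma_cross(c(0, 1, 0), z)
  x <- x / sqrt(sum(x^2))
  y <- pracma_cross(z, x)
  rigid_transform(cbind(x, y, z), eye)
}

#' Simulate a tracked hand-eye calibration session
#'
#' Generates `n_captures` tracked captures with known ground truth: the board
#' is placed with randomised tilt near the tracking-volume origin, the camera
#' optical centre is placed on a randomised standoff looking at the board
#' (rejection-sampled so all corners stay in the frustum), exact M and V
#' follow from the ground-truth E and G, then tracking jitter perturbs the
#' rigid-body poses and Gaussian pixel noise perturbs the projected corners.
#' The stored board pose `v` is re-estimated from the (noisy) corners with
#' [estimate_board_pose()], exactly as in a real session.
#'
#' @param e_true ground-truth mount transform E (optical centre to camera
#'   rigid body).
#' @param g_true ground-truth board mount transform G.
#' @param intr `camera_intrinsics`.
#' @param board `checkerboard`.
#' @param n_captures number of captures (default 15, the protocol scale).
#' @param tracking_noise_ a `tracking_noise`.
#' @param corner_noise_px corner detection noise std (px).
#' @param seed integer seed.
#' @return List of `tracked_capture`.
#' @export
simulate_calibration_session <- function(e_true, g_true, intr, board,
                                         n_captures = 15L,
                                         tracking_noise_ = tracking_noise(0, 0),
                                         corner_noise_px = 0, seed = 1L) {
  stopifnot(n_captures >= 3L)
  with_seed(seed, {
    captures <- vector("list", n_captures)
    board_ctr <- colMeans(board$corner_points)
    for (i in seq_len(n_captures)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        # board geometry frame in the tracking volume
        tilt <- compose(axis_rotation("x", stats::runif(1, -25, 25)),
                        axis_rotation("y", stats::runif(1, -25, 25)))
        t_w_b <- compose(rigid_transform(diag(3), stats::runif(3, -80, 80)),
                         tilt)
        # optical centre on a standoff in front of the board
        nrm_w <- as.numeric(t_w_b$R %*% c(0, 0, 1))
        ctr_w <- as.numeric(transform_points(t_w_b, board_ctr))
        d <- stats::runif(1, 380, 620)
        side <- stats::rnorm(3, 0, 0.25); side <- side - sum(side * nrm_w) * nrm_w
        dir <- nrm_w + side; dir <- dir / sqrt(sum(dir^2))
        eye <- ctr_w - dir * d
        t_w_o <- look_at_pose(eye, ctr_w + stats::rnorm(3, 0, 15))
        v_true <- compose(invert(t_w_o), t_w_b)
        proj <- tryCatch(project_points(intr, v_true, board$corner_points),
                         error = function(e) NULL)
        if (is.null(proj)) next
        inside <- proj[, 1] >= 2 & proj[, 1] < intr$width - 2 &
          proj[, 2] >= 2 & proj[, 2] < intr$height - 2
        if (all(inside)) { ok <- TRUE; break }
      }
      if (!ok) stop("geometry error: could not place board in frustum")
      m_cam <- simulate_tracked_pose(compose(t_w_o, invert(e_true)),
                                     tracking_noise_)
      m_board <- simulate_tracked_pose(compose(t_w_b, g_true), tracking_noise_)
      obs <- corner_observation(proj + matrix(
        stats::rnorm(length(proj), 0, corner_noise_px), ncol = 2L),
        capture_id = sprintf("capture_%02d", i))
      v_est <- estimate_board_pose(intr, board, obs)
      captures[[i]] <- tracked_capture(m_cam, m_board, v_est, corners = obs,
                                       capture_id = obs$capture_id)
    }
    captures
  })
}

#' Depth-camera noise preset
#'
#' Describes one depth-sensing configuration: axial (along-ray) noise, lateral
#' jitter, dropout, optional depth quantisation and the working depth range.
#' The built-in presets mirror the five commercial cameras (seven
#' configurations) of the evaluation; their noise magnitudes are this
#' package's own estimates of each technology class, not manufacturer or
#' measured figures.
#'
#' @param name identifier.
#' @param axial_sigma_mm depth noise std along the viewing ray (mm).
#' @param lateral_sigma_mm in-plane jitter std (mm).
#' @param dropout_rate i.i.d. fraction of points removed.
#' @param quantization_mm depth rounding step (0 = off).
#' @param range_min_mm,range_max_mm working depth range (mm).
#' @return An object of class `camera_noise_preset`.
#' @export
camera_noise_preset <- function(name, axial_sigma_mm, lateral_sigma_mm = 0,
                                dropout_rate = 0, quantization_mm = 0,
                                range_min_mm = 50, range_max_mm = 1000) {
  stopifnot(axial_sigma_mm >= 0, lateral_sigma_mm >= 0, dropout_rate >= 0,
            dropout_rate < 1, quantization_mm >= 0,
            range_min_mm < range_max_mm, range_min_mm >= 0)
  structure(list(name = name, axial_sigma_mm = axial_sigma_mm,
                 lateral_sigma_mm = lateral_sigma_mm,
                 dropout_rate = dropout_rate,
                 quantization_mm = quantization_mm,
                 range_min_mm = range_min_mm, range_max_mm = range_max_mm),
            class = "camera_noise_preset")
}

#' Built-in camera noise presets
#'
#' Seven presets covering the five evaluated cameras and the two feature
#' toggles (D435f without its dot projector, Zed-M with and without neural
#' depth refinement). Depth ranges follow the manufacturers' specifications;
#' noise magnitudes are own estimates chosen so that texture-projector /
#' refinement toggles reproduce the overlap-exclusion behaviour in kind. The
#' untextured-stereo configurations (d435f-no-projector, oak-d, zed-m) carry
#' inflated axial noise and dropout.
#'
#' @return Named list of 7 `camera_noise_preset` objects.
#' @export
builtin_presets <- function() {
  ps <- list(
    camera_noise_preset("d405", axial_sigma_mm = 0.4, lateral_sigma_mm = 0.15,
                        dropout_rate = 0.02, range_min_mm = 70,
                        range_max_mm = 500),
    camera_noise_preset("d435f", axial_sigma_mm = 0.9, lateral_sigma_mm = 0.25,
                        dropout_rate = 0.03, range_min_mm = 300,
                        range_max_mm = 3000),
    camera_noise_preset("d435f-no-projector", axial_sigma_mm = 6.0,
                        lateral_sigma_mm = 0.8, dropout_rate = 0.45,
                        range_min_mm = 300, range_max_mm = 3000),
    camera_noise_preset("zed-m", axial_sigma_mm = 5.0, lateral_sigma_mm = 0.7,
                        dropout_rate = 0.35, range_min_mm = 100,
                        range_max_mm = 9000),
    camera_noise_preset("zed-m-plus", axial_sigma_mm = 0.8,
                        lateral_sigma_mm = 0.3, dropout_rate = 0.03,
                        range_min_mm = 100, range_max_mm = 9000),
    camera_noise_preset("oak-d", axial_sigma_mm = 5.5, lateral_sigma_mm = 0.7,
                        dropout_rate = 0.40, range_min_mm = 300,
                        range_max_mm = 1000),
    camera_noise_preset("photoneo-s", axial_sigma_mm = 0.3,
                        lateral_sigma_mm = 0.1, dropout_rate = 0.01,
                        quantization_mm = 0.1, range_min_mm = 330,
                        range_max_mm = 550)
  )
  stats::setNames(ps, vapply(ps, `[[`, "", "name"))
}

#' Write and read the preset registry as YAML
#' @param presets named list of `camera_noise_preset`.
#' @param path file path.
#' @return `read_presets` returns such a list.
#' @export
write_presets <- function(presets, path) {
  yaml::write_yaml(lapply(presets, unclass), path, precision = 17)
  invisible(path)
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  v <- yaml::read_yaml(path)
  stats::setNames(lapply(v, function(e) do.call(camera_noise_preset, e)),
                  vapply(v, `[[`, "", "name"))
}

#' Simulate one depth capture of the phantom
#'
#' Renders the scene from a camera pose: points are expressed in the optical
#' frame, culled by depth range and outward-normal orientation, hidden
#' surfaces removed by a z-buffer over a virtual 640x480 pixel grid, then
#' perturbed axially along the viewing ray and laterally across it, thinned by
#' i.i.d. dropout and optionally depth-quantised.
#'
#' @param scene `phantom_scene`.
#' @param camera_pose camera-to-scene `rigid_transform` (pose of the optical
#'   frame in the phantom frame).
#' @param preset `camera_noise_preset`.
#' @param seed integer seed.
#' @param keep_labels return region labels of surviving points as an
#'   attribute.
#' @return N x 3 matrix of optical-frame points (mm), with attribute `labels`
#'   when requested.
#' @export
simulate_depth_capture <- function(scene, camera_pose, preset, seed = 1L,
                                   keep_labels = TRUE) {
  with_seed(seed, {
    t_cam <- invert(camera_pose)
    pc <- transform_points(t_cam, scene$surface_points)
    nc <- scene$normals %*% t(t_cam$R)
    keep <- pc[, 3] >= preset$range_min_mm & pc[, 3] <= preset$range_max_mm
    ray <- pc / sqrt(rowSums(pc^2))
    keep <- keep & rowSums(nc * ray) < -0.05
    if (!any(keep)) {
      stop("visibility error: no scene points visible from this pose")
    }
    pc <- pc[keep, , drop = FALSE]
    labs <- scene$region_labels[keep]
    # z-buffer on a virtual pixel grid (fx = fy = 580, 640x480)
    u <- round(580 * pc[, 1] / pc[, 3] + 320)
    v <- round(580 * pc[, 2] / pc[, 3] + 240)
    vis <- u >= 0 & u < 640 & v >= 0 & v < 480
    pc <- pc[vis, , drop = FALSE]; labs <- labs[vis]
    u <- u[vis]; v <- v[vis]
    pix <- u * 480 + v
    ord <- order(pix, pc[, 3])
    first <- !duplicated(pix[ord])
    # a pixel may legitimately hold several samples of the same front surface;
    # keep all samples within 2 mm depth of the pixel's nearest hit
    zmin <- stats::ave(pc[ord, 3], pix[ord], FUN = min)
    sel <- ord[pc[ord, 3] <= zmin + 2]
    pc <- pc[sel, , drop = FALSE]; labs <- labs[sel]
    if (nrow(pc) == 0L) stop("visibility error: empty visible set")
    n <- nrow(pc)
    ray <- pc / sqrt(rowSums(pc^2))
    if (preset$axial_sigma_mm > 0) {
      pc <- pc + ray * stats::rnorm(n, 0, preset$axial_sigma_mm)
    }
    if (preset$lateral_sigma_mm > 0) {
      up <- matrix(rep(c(0, 1, 0), each = n), ncol = 3L)
      e1 <- cbind(ray[, 2] * up[, 3] - ray[, 3] * up[, 2],
                  ray[, 3] * up[, 1] - ray[, 1] * up[, 3],
                  ray[, 1] * up[, 2] - ray[, 2] * up[, 1])
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(ray[, 2] * e1[, 3] - ray[, 3] * e1[, 2],
                  ray[, 3] * e1[, 1] - ray[, 1] * e1[, 3],
                  ray[, 1] * e1[, 2] - ray[, 2] * e1[, 1])
      pc <- pc + e1 * stats::rnorm(n, 0, preset$lateral_sigma_mm) +
        e2 * stats::rnorm(n, 0, preset$lateral_sigma_mm)
    }
    if (preset$quantization_mm > 0) {
      d <- sqrt(rowSums(pc^2))
      dq <- round(d / preset$quantization_mm) * preset$quantization_mm
      pc <- pc * (dq / d)
    }
    if (preset$dropout_rate > 0) {
      keep2 <- stats::runif(n) >= preset$dropout_rate
      pc <- pc[keep2, , drop = FALSE]; labs <- labs[keep2]
    }
    d <- sqrt(rowSums(pc^2))
    inr <- pc[, 3] >= preset$range_min_mm & pc[, 3] <= preset$range_max_mm
    pc <- pc[inr, , drop = FALSE]; labs <- labs[inr]
    if (nrow(pc) == 0L) stop("visibility error: empty cloud after noise")
    if (keep_labels) attr(pc, "labels") <- labs
    pc
  })
}

#' Export a phantom scene
#'
#' Writes the surface as PLY (xyz + normals + a uchar label channel), the
#' fiducials as CSV and the craniotomy bounding box as JSON.
#'
#' @param scene `phantom_scene`.
#' @param dir output directory (created if needed).
#' @param binary write binary-little-endian PLY (default) or ascii.
#' @return Invisibly, the directory.
#' @export
export_scene <- function(scene, dir, binary = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lvl <- c(face = 0L, scalp = 1L, craniotomy = 2L, other = 3L)
  write_ply(file.path(dir, "phantom.ply"), scene$surface_points,
            normals = scene$normals,
            labels = lvl[scene$region_labels], binary = binary)
  utils::write.csv(data.frame(fid = seq_len(nrow(scene$fiducials)),
                              x_mm = scene$fiducials[, 1],
                              y_mm = scene$fiducials[, 2],
                              z_mm = scene$fiducials[, 3]),
                   file.path(dir, "fiducials.csv"), row.names = FALSE)
  jsonlite::write_json(list(min_mm = scene$craniotomy_box[1, ],
                            max_mm = scene$craniotomy_box[2, ]),
                       file.path(dir, "craniotomy_box.json"), digits = NA)
  invisible(dir)
}
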