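#' Specification of a synthetic RGB-D target scene
#'
#' Describes a table-top scene of green ball targets as seen by the
#' RGB-D camera: 2-4 targets at a common working depth (with a small
#' per-target depth jitter), pairwise separations controlled within
#' 0.15-0.35 m, ball radius 0.035 m (7 cm diameter). When
#' `target_positions` is `NULL`, positions are sampled from the spec's
#' seed under those constraints.
#'
#' @param n_targets number of targets (2, 3 or 4).
#' @param seed integer seed fixing the sampled layout.
#' @param target_positions optional n x 3 matrix of Kinect-frame positions
#'   (metres) overriding the sampler; separations are still validated.
#' @param disk_radius target ball radius in metres.
#' @param background background RGB triple in \[0, 255\].
#' @param depth_range range (metres) from which the scene's working depth
#'   is drawn.
#' @param separation allowed range of pairwise target separations (metres).
#' @param width,height image dimensions in pixels.
#' @return Object of class `scene_spec` (target positions resolved).
#' @export
scene_spec <- function(n_targets = 2, seed = 1, target_positions = NULL,
                       disk_radius = 0.035, background = c(128, 128, 128),
                       depth_range = c(0.9, 1.1),
                       separation = c(0.15, 0.35),
                       width = 640, height = 480) {
  stopifnot(n_targets %in% 2:4, length(background) == 3L,
            all(background >= 0 & background <= 255),
            disk_radius > 0, separation[1] > 0, separation[2] > separation[1])
  if (is.null(target_positions)) {
    target_positions <- withr_seed(seed, .sample_layout(
      n_targets, depth_range, separation))
  } else {
    target_positions <- as.matrix(target_positions)
    stopifnot(nrow(target_positions) == n_targets,
              ncol(target_positions) == 3L)
  }
  sep <- stats::dist(target_positions)
  if (any(sep < separation[1] - 1e-12 | sep > separation[2] + 1e-12))
    stop("scene_spec: pairwise target separations must lie within [",
         separation[1], ", ", separation[2], "] m")
  structure(list(n_targets = n_targets, seed = seed,
                 target_positions = target_positions,
                 disk_radius = disk_radius, background = background,
                 width = width, height = height),
            class = "scene_spec")
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# rejection-sample target positions: common depth, lateral separations
.sample_layout <- function(n, depth_range, separation, max_tries = 10000L) {
  for (tr in seq_len(max_tries)) {
    z0 <- stats::runif(1, depth_range[1], depth_range[2])
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- c(stats::runif(1, -0.15, 0.15), stats::runif(1, -0.1, 0.1),
                  z0 + stats::runif(1, -0.02, 0.02))
    ok <- TRUE
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      for (att in 1:50) {
        anchor <- pos[sample.int(i - 1L, 1L), ]
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, separation[1] + 0.02, separation[2] - 0.02)
        cand <- c(anchor[1] + d * cos(ang), anchor[2] + d * sin(ang),
                  z0 + stats::runif(1, -0.02, 0.02))
        if (abs(cand[1]) > 0.3 || abs(cand[2]) > 0.22) next
        seps <- sqrt(colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) -
                                cand)^2))
        if (all(seps >= separation[1] + 0.01 & seps <= separation[2] - 0.01)) {
          pos[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("scene layout sampling failed; constraints too tight")
}

#' Render a synthetic RGB-D scene
#'
#' Inverts the camera model of the supplied calibration to paint green
#' target disks at the pixel and depth-index coordinates a real camera
#' would have produced for the spec's Kinect-frame target positions. The
#' depth image is painted so that the depth pixel mapped from each RGB
#' centroid carries exactly that target's depth index; the background sits
#' at 2 m.
#'
#' @param spec a `scene_spec`.
#' @param model a `calibration_model` (the renderer and the localizer must
#'   share it for round-trips to close).
#' @return Object of class `synthetic_scene`: list with `rgb`
#'   (H x W x 3 array), `depth` (H x W matrix of depth indices), and
#'   `truth` (data.frame: `id`, Kinect-frame `x`, `y`, `z`, and the exact
#'   projected `pixel_x`, `pixel_y`).
#' @export
render_scene <- function(spec, model = default_calibration()) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  cx <- w / 2; cy <- h / 2
  rgb <- array(rep(spec$background, each = h * w), dim = c(h, w, 3))
  bg_index <- (2.0 - model$depth_intercept) / model$depth_slope
  depth <- matrix(bg_index, h, w)

  n <- spec$n_targets
  truth <- data.frame(id = seq_len(n), x = NA_real_, y = NA_real_,
                      z = NA_real_, pixel_x = NA_real_, pixel_y = NA_real_)
  centers <- matrix(NA_real_, n, 2)
  radii <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    p <- spec$target_positions[i, ]
    d <- p[3]
    mx <- model$x_coeff[1] * d + model$x_coeff[2]  # metres per pixel, x
    my <- model$y_coeff[1] * d + model$y_coeff[2]
    px <- cx + p[1] / mx
    py <- cy + p[2] / my
    rx <- spec$disk_radius / mx
    ry <- spec$disk_radius / abs(my)
    if (px - rx < 3 || px + rx > w - 4 || py - ry < 3 || py + ry > h - 4)
      stop(sprintf("render_scene: target %d projects outside the frame", i))
    centers[i, ] <- c(px, py); radii[i, ] <- c(rx, ry)
    truth[i, 2:6] <- c(p, px, py)
  }
  for (i in seq_len(n))
    for (j in seq_len(n)[-1 * seq_len(i)]) {
      gap <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (gap < max(radii[i, 1] + radii[j, 1], radii[i, 2] + radii[j, 2]) + 6)
        stop("render_scene: target disks overlap in the image")
    }

  for (i in seq_len(n)) {
    rgb <- .paint_ellipse_rgb(rgb, centers[i, ], radii[i, ], c(40, 200, 40))
    dp <- map_rgb_to_depth(centers[i, ], model$B)
    didx <- (spec$target_positions[i, 3] - model$depth_intercept) /
      model$depth_slope
    depth <- .paint_ellipse_depth(depth, dp, radii[i, ] * 1.3 + 3, didx)
  }
  structure(list(rgb = rgb, depth = depth, truth = truth, spec = spec),
            class = "synthetic_scene")
}

# paint an axis-aligned ellipse; center/radii in 0-based (x, y) pixels
.ellipse_mask <- function(h, w, center, radii) {
  rows <- max(1, floor(center[2] - radii[2])):min(h, ceiling(center[2] + radii[2] + 2))
  cols <- max(1, floor(center[1] - radii[1])):min(w, ceiling(center[1] + radii[1] + 2))
  yy <- (rows - 1 - center[2]) / radii[2]
  xx <- (cols - 1 - center[1]) / radii[1]
  m <- outer(yy^2, xx^2, `+`) <= 1
  list(rows = rows, cols = cols, mask = m)
}

.paint_ellipse_rgb <- function(rgb, center, radii, colour) {
  em <- .ellipse_mask(dim(rgb)[1], dim(rgb)[2], center, radii)
  for (ch in 1:3) {
    block <- rgb[em$rows, em$cols, ch]
    block[em$mask] <- colour[ch]
    rgb[em$rows, em$cols, ch] <- block
  }
  rgb
}

.paint_ellipse_depth <- function(depth, center, radii, value) {
  em <- .ellipse_mask(nrow(depth), ncol(depth), center, radii)
  block <- depth[em$rows, em$cols]
  block[em$mask] <- value
  depth[em$rows, em$cols] <- block
  depth
}

#' Specification of synthetic decoded-velocity trajectories
#'
#' Emulates the statistics of hand-velocity streams decoded from
#' noninvasive neural signals during directional reaching: per trial, the
#' noise-free velocity always points from the current ideal position to
#' the trial's target with a fixed step length, and the decoded velocity
#' is that vector perturbed by a random rotation (rotation-vector noise,
#' per-axis sd `angular_noise_sd`) and a multiplicative magnitude
#' perturbation. An optional AR(1) coefficient correlates the rotation
#' noise across steps (off by default).
#'
#' @param n_directions number of reaching directions (one target each).
#' @param trials_per_direction trials per direction (default 30, so the
#'   default ensemble is 4 x 30 = 120 trials).
#' @param n_steps decoded samples per trial.
#' @param base_step noise-free step length in metres; the default
#'   0.008 m x 50 steps covers a 0.4 m reach.
#' @param angular_noise_sd per-axis sd of the rotation-vector noise,
#'   radians.
#' @param magnitude_noise_sd sd of the multiplicative magnitude noise
#'   (fraction).
#' @param ar1 AR(1) coefficient of the rotation noise in \[0, 1).
#' @param seed integer seed; generated ensembles are reproducible
#'   bit-for-bit from the spec.
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_directions = 4, trials_per_direction = 30,
                            n_steps = 50, base_step = 0.008,
                            angular_noise_sd = 0.6,
                            magnitude_noise_sd = 0.2,
                            ar1 = 0, seed = 1) {
  stopifnot(n_directions >= 1, trials_per_direction >= 1, n_steps >= 1,
            is.numeric(base_step),
            angular_noise_sd >= 0, magnitude_noise_sd >= 0,
            ar1 >= 0, ar1 < 1)
  if (base_step <= 0) stop("trajectory_spec: base_step must be positive")
  structure(list(n_directions = as.integer(n_directions),
                 trials_per_direction = as.integer(trials_per_direction),
                 n_steps = as.integer(n_steps), base_step = base_step,
                 angular_noise_sd = angular_noise_sd,
                 magnitude_noise_sd = magnitude_noise_sd,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate synthetic decoded trajectories
#'
#' Direction `d` reaches for the `d`-th target of `targets`. Each returned
#' trial is a `decoded_trajectory`: list with `velocities` (n_steps x 3),
#' `true_target_id` and `direction_label`.
#'
#' @param spec a `trajectory_spec`; `n_directions` must not exceed the
#'   number of targets.
#' @param targets a `target_set` (frame 0).
#' @param start length-3 start position of the reach (frame 0, metres).
#' @return List of `decoded_trajectory` objects, directions interleaved in
#'   trial order (direction 1 trial 1, direction 2 trial 1, ...).
#' @export
generate_trials <- function(spec, targets, start) {
  stopifnot(inherits(spec, "trajectory_spec"),
            inherits(targets, "target_set"))
  if (spec$n_directions > length(targets$ids))
    stop("generate_trials: n_directions exceeds the number of targets")
  start <- as.numeric(start)
  stopifnot(length(start) == 3L)
  withr_seed(spec$seed, {
    trials <- vector("list", spec$n_directions * spec$trials_per_direction)
    k <- 0L
    for (rep in seq_len(spec$trials_per_direction)) {
      for (d in seq_len(spec$n_directions)) {
        k <- k + 1L
        id <- targets$ids[d]
        tpos <- targets$positions[d, ]
        trials[[k]] <- .one_trial(spec, tpos, id, d, start)
      }
    }
    trials
  })
}

.one_trial <- function(spec, tpos, id, direction, start) {
  pos <- start
  vel <- matrix(0, spec$n_steps, 3)
  wprev <- c(0, 0, 0)
  for (k in seq_len(spec$n_steps)) {
    diff <- tpos - pos
    dist <- sqrt(sum(diff^2))
    if (dist == 0) {
      true_v <- c(0, 0, 0)
    } else {
      true_v <- diff / dist * min(spec$base_step, dist)
    }
    w <- spec$ar1 * wprev +
      sqrt(1 - spec$ar1^2) * stats::rnorm(3, 0, spec$angular_noise_sd)
    wprev <- w
    mag <- max(0, 1 + stats::rnorm(1, 0, spec$magnitude_noise_sd))
    vel[k, ] <- .rotate_by_vector(true_v, w) * mag
    pos <- pos + true_v                      # ideal path integrates true_v
  }
  structure(list(velocities = vel, true_target_id = id,
                 direction_label = direction),
            class = "decoded_trajectory")
}

# rotate v by the rotation vector w (axis w/|w|, angle |w|), Rodrigues
.rotate_by_vector <- function(v, w) {
  th <- sqrt(sum(w^2))
  if (th == 0) return(v)
  k <- w / th
  v * cos(th) + .cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.decoded_trajectory <- function(x, ...) {
  cat(sprintf(
    "<decoded_trajectory> %d steps, direction %d, true target %d\n",
    nrow(x$velocities), x$direction_label, x$true_target_id))
  invisible(x)
}

#' Default reaching layout of the simulated rig
#'
#' A reproducible frame-0 geometry for the four-direction reaching task:
#' the end-effector starts at `(0.40, 0, -0.10)` m and the four targets sit
#' about 0.4 m away toward the four front quadrants (up-left, up-right,
#' down-left, down-right of the reach axis). All positions are reachable
#' and away from the shoulder singularity.
#'
#' @param dh a `dh_table`.
#' @param elbow elbow branch for goal configurations.
#' @return List with `targets` (a `target_set`), `start_position` and
#'   `start_config`.
#' @export
default_reach_layout <- function(dh = dh_table(), elbow = "up") {
  s <- c(0.40, 0, -0.10)
  pos <- rbind(s + c(0.25, 0.25, 0.15),
               s + c(0.25, -0.25, 0.15),
               s + c(0.25, 0.25, -0.15),
               s + c(0.25, -0.25, -0.15))
  list(targets = target_set(pos, dh = dh, elbow = elbow),
       start_position = s,
       start_config = arm_inverse(s, dh, elbow))
}

#' Write a decoded trajectory as CSV
#'
#' Columns `vx`, `vy`, `vz` (metres per step), one row per decoded sample.
#'
#' @param trajectory a `decoded_trajectory`.
#' @param path output path.
#' @export
write_trial <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "decoded_trajectory"))
  utils::write.csv(data.frame(vx = trajectory$velocities[, 1],
                              vy = trajectory$velocities[, 2],
                              vz = trajectory$velocities[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a decoded trajectory from CSV
#'
#' @param path CSV with columns `vx`, `vy`, `vz`.
#' @param true_target_id,direction_label optional metadata.
#' @return A `decoded_trajectory`.
#' @export
read_trial <- function(path, true_target_id = NA_integer_,
                       direction_label = NA_integer_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("vx", "vy", "vz") %in% names(df)))
  structure(list(velocities = as.matrix(df[, c("vx", "vy", "vz")]),
                 true_target_id = true_target_id,
                 direction_label = direction_label),
            class = "decoded_trajectory")
}
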