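#' Candidate target set for shared control
#'
#' Holds the metric positions of the candidate targets (frame 0 of the arm)
#' together with their goal joint configurations `q_g` obtained by inverse
#' kinematics. The goal configurations are what the attractive potential
#' acts on.
#'
#' @param positions n x 3 matrix of target positions in frame 0, metres;
#'   every target must be reachable.
#' @param ids integer target ids (unique); default `1:n`.
#' @param dh a `dh_table`.
#' @param elbow elbow branch passed to [arm_inverse()].
#' @return Object of class `target_set` with elements `ids`, `positions`
#'   (n x 3) and `goal_configs` (n x 3 joint angles).
#' @export
target_set <- function(positions, ids = seq_len(nrow(positions)),
                       dh = dh_table(), elbow = "up") {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 1L,
            all(is.finite(positions)))
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("target_set: target ids must be unique")
  ord <- order(ids)
  positions <- positions[ord, , drop = FALSE]
  ids <- ids[ord]
  goals <- t(apply(positions, 1, arm_inverse, dh = dh, elbow = elbow))
  dimnames(positions) <- dimnames(goals) <- NULL
  structure(list(ids = ids, positions = positions, goal_configs = goals,
                 dh = dh),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set>", length(x$ids), "targets (frame 0)\n")
  print(data.frame(id = x$ids, x = x$positions[, 1], y = x$positions[, 2],
                   z = x$positions[, 3]))
  invisible(x)
}

#' Shared-control blending parameters
#'
#' `alpha` weighs the vision-derived ideal direction against the decoded
#' hand velocity in each compensation vector; `beta` is the inertia weight
#' mixing the current compensation vector with the previous one, which
#' suppresses sudden unintended movements. Both range over \[0, 1\];
#' `alpha = 1, beta = 1` is fully machine-guided (observation-based
#' training), `alpha = 0` passes the decoded command through untouched.
#'
#' @param alpha,beta blending parameters in \[0, 1\].
#' @param step_scale gain applied to every compensation vector; the rig
#'   uses 1.5.
#' @param reach_tolerance stop radius in metres: a trial ends once the
#'   end-effector is within this distance of any target. 0.02 m by default
#'   (a 1-2 cm deviation is tolerable given gripper and ball sizes);
#'   0 disables early stopping.
#' @param max_steps cap on the number of control steps; default unlimited
#'   (the decoded stream length bounds the trial).
#' @return Object of class `shared_control_params`.
#' @export
shared_control_params <- function(alpha, beta, step_scale = 1.5,
                                  reach_tolerance = 0.02, max_steps = Inf) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(step_scale), step_scale > 0,
            is.numeric(reach_tolerance), reach_tolerance >= 0,
            max_steps >= 1)
  structure(list(alpha = alpha, beta = beta, step_scale = step_scale,
                 reach_tolerance = reach_tolerance, max_steps = max_steps),
            class = "shared_control_params")
}

#' Infer the intended target from the decoded velocity
#'
#' The intended target is the candidate whose direction from the current
#' end-effector position makes the smallest angle with the decoded velocity
#' vector. It is re-inferred at every waypoint step, so the user can change
#' the preferred target mid-trial. Ties go to the lowest target id. A
#' target coincident with the current position is reported as reached
#' (returned immediately); a zero decoded velocity carries no intent and
#' yields `NA`.
#'
#' @param velocity length-3 decoded velocity vector.
#' @param position length-3 current end-effector position (frame 0).
#' @param targets a `target_set`.
#' @return The intended target id, or `NA_integer_` for zero velocity.
#' @export
infer_intended_target <- function(velocity, position, targets) {
  v <- as.numeric(velocity); p <- as.numeric(position)
  stopifnot(length(v) == 3L, length(p) == 3L, inherits(targets, "target_set"))
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NA_integer_)
  d <- sweep(targets$positions, 2, p)
  nd <- sqrt(rowSums(d^2))
  if (any(nd == 0)) return(targets$ids[which(nd == 0)[1L]])
  cosang <- (d %*% v) / (nd * nv)
  targets$ids[which.max(cosang)]           # which.max: first max = lowest id
}

#' Attractive potential step toward the intended target
#'
#' Each target i exerts an attractive force `f_a,i = k_a,i * e_i` in joint
#' space, with `e_i = q_g,i - q` and stiffness `k_a,i = 1` for the intended
#' target and 0 otherwise. The ideal Cartesian direction is the
#' end-effector displacement the total force would produce:
#' `dx_i = x_e(q + f_t) - x_e(q)`. Because the stiffness is the indicator
#' of the intended target, `q + f_t` is exactly the intended goal
#' configuration, so `dx_i` equals `target_position - current_position`.
#'
#' @param q length-3 current joint configuration.
#' @param intended intended target id.
#' @param targets a `target_set`.
#' @return Length-3 ideal displacement vector (metres).
#' @export
attract <- function(q, intended, targets) {
  stopifnot(inherits(targets, "target_set"))
  i <- match(intended, targets$ids)
  if (is.na(i))
    stop("attract: target id ", intended, " not in the target set")
  q <- as.numeric(q)
  ka <- as.numeric(targets$ids == targets$ids[i])
  e <- sweep(targets$goal_configs, 2, q)   # e_i = q_g,i - q
  ft <- colSums(ka * e)
  dh <- targets$dh
  .fk_pos(q + ft, dh$a2, dh$a3) - .fk_pos(q, dh$a2, dh$a3)
}

#' Blend the decoded velocity with the ideal direction
#'
#' The ideal direction is rescaled to the magnitude of the decoded
#' velocity, then the two are mixed with weights `alpha` and `1 - alpha`
#' and scaled by `step_scale`:
#' `dx = step_scale * (alpha * |decoded| * unit(ideal) +
#' (1 - alpha) * decoded)`. Consequently `|dx| <= step_scale * |decoded|`,
#' with equality at `alpha` 0 or 1.
#'
#' @param decoded length-3 decoded hand velocity.
#' @param ideal length-3 ideal displacement toward the intended target;
#'   must be nonzero when `alpha > 0`.
#' @param alpha blending weight in \[0, 1\].
#' @param step_scale scale factor (default 1.5).
#' @return Length-3 compensation vector.
#' @export
blend <- function(decoded, ideal, alpha, step_scale = 1.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("blend: alpha must be a single value in [0, 1]")
  v <- as.numeric(decoded); u <- as.numeric(ideal)
  stopifnot(length(v) == 3L, length(u) == 3L)
  nu <- sqrt(sum(u^2))
  if (alpha > 0 && nu == 0)
    stop("blend: ideal direction is zero but alpha > 0")
  nv <- sqrt(sum(v^2))
  scaled_ideal <- if (nu == 0) c(0, 0, 0) else nv * u / nu
  step_scale * (alpha * scaled_ideal + (1 - alpha) * v)
}

#' Apply one control step with inertia
#'
#' The applied displacement mixes the current compensation vector with the
#' previous one, `s_k = beta * dx_k + (1 - beta) * dx_(k-1)` (the first
#' applied step uses `dx_k` alone). The new position is solved back to a
#' joint configuration; a step that would leave the reachable workspace is
#' clamped at the boundary along its direction and flagged.
#'
#' @param position length-3 current end-effector position.
#' @param blended length-3 compensation vector `dx_k` (see [blend()]).
#' @param beta inertia weight in \[0, 1\].
#' @param previous length-3 previous compensation vector, or `NULL` on the
#'   first applied step.
#' @param dh a `dh_table`.
#' @param elbow elbow branch for the IK solve.
#' @return List with `position`, `config`, `displacement` and logical
#'   `clamped`.
#' @export
control_step <- function(position, blended, beta, previous = NULL,
                         dh = dh_table(), elbow = "up") {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1)
    stop("control_step: beta must be a single value in [0, 1]")
  p <- as.numeric(position); dx <- as.numeric(blended)
  s <- if (is.null(previous)) dx else beta * dx + (1 - beta) * as.numeric(previous)
  new_p <- p + s
  clamped <- FALSE
  margin <- 1e-9
  lo <- abs(dh$a2 - dh$a3) + margin; hi <- dh$a2 + dh$a3 - margin
  nn <- sqrt(sum(new_p^2))
  if (nn > hi || nn < lo) {
    t_hit <- .clamp_to_annulus(p, s, lo, hi)
    new_p <- p + t_hit * s
    s <- t_hit * s
    clamped <- TRUE
  }
  q <- suppressWarnings(arm_inverse(new_p, dh, elbow))
  list(position = new_p, config = q, displacement = s, clamped = clamped)
}

# largest t in [0, 1] with p + t*s inside the annulus [lo, hi]
.clamp_to_annulus <- function(p, s, lo, hi) {
  f <- function(t) sqrt(sum((p + t * s)^2))
  inside <- function(t) { r <- f(t); r >= lo && r <= hi }
  if (!inside(0)) return(0)
  a <- 0; b <- 1
  for (i in 1:60) {
    m <- (a + b) / 2
    if (inside(m)) a <- m else b <- m
  }
  a
}

#' Run one shared-control trial
#'
#' Iterates over a decoded velocity stream and emits the end-effector
#' waypoint sequence. Per step: infer the intended target from the decoded
#' velocity; if the decoded velocity moves away from the start position
#' (non-negative component along `position - start`) and makes an angle of
#' less than 90 degrees with the direction to the intended target, blend
#' and step; otherwise hold position (the unchanged waypoint is still
#' emitted, keeping waypoints aligned with the velocity stream). The trial
#' stops early once within `reach_tolerance` of any target.
#'
#' @param trajectory a `decoded_trajectory` (see [generate_trials()]) or an
#'   n x 3 matrix of decoded velocity vectors.
#' @param targets a `target_set`.
#' @param params a `shared_control_params`.
#' @param start_config length-3 starting joint configuration.
#' @param elbow elbow branch used for IK solves during the trial.
#' @return Object of class `reach_trial`: list with `waypoints`
#'   ((k+1) x 3 matrix including the start), `intended` (target id per
#'   step), `gated` and `clamped` (logical per step), `reached` (id of the
#'   target that stopped the trial or `NA`), `n_steps`, `params`, and the
#'   input metadata.
#' @export
run_trial <- function(trajectory, targets, params, start_config,
                      elbow = "up") {
  stopifnot(inherits(targets, "target_set"),
            inherits(params, "shared_control_params"))
  vel <- if (inherits(trajectory, "decoded_trajectory"))
    trajectory$velocities else as.matrix(trajectory)
  if (!is.null(dim(vel)) && ncol(vel) != 3L)
    stop("run_trial: decoded velocities must be an n x 3 matrix")
  q <- normalize_angle(as.numeric(start_config))
  dh <- targets$dh
  pos <- .fk_pos(q, dh$a2, dh$a3)
  start_pos <- pos
  n <- if (is.null(nrow(vel))) 0L else min(nrow(vel), params$max_steps)

  wp <- matrix(NA_real_, n + 1L, 3L)
  wp[1L, ] <- pos
  intended <- integer(n); gated <- logical(n); clamped <- logical(n)
  prev_dx <- NULL
  reached <- NA_integer_
  k_last <- 0L
  for (k in seq_len(n)) {
    v <- vel[k, ]
    id <- infer_intended_target(v, pos, targets)
    intended[k] <- id
    hold <- TRUE
    if (!is.na(id)) {
      tdir <- targets$positions[match(id, targets$ids), ] - pos
      away <- sum(v * (pos - start_pos)) >= 0
      toward <- sum(v * tdir) > 0
      if (away && toward) {
        dxi <- attract(q, id, targets)
        dxk <- blend(v, dxi, params$alpha, params$step_scale)
        st <- control_step(pos, dxk, params$beta, prev_dx, dh, elbow)
        pos <- st$position; q <- st$config
        clamped[k] <- st$clamped
        prev_dx <- dxk
        hold <- FALSE
      }
    }
    gated[k] <- hold
    wp[k + 1L, ] <- pos
    k_last <- k
    if (params$reach_tolerance > 0) {
      dists <- sqrt(rowSums(sweep(targets$positions, 2, pos)^2))
      if (any(dists <= params$reach_tolerance)) {
        reached <- targets$ids[which.min(dists)]
        break
      }
    }
  }
  keep <- seq_len(k_last)
  structure(list(
    waypoints = wp[c(1L, keep + 1L), , drop = FALSE],
    intended = intended[keep], gated = gated[keep], clamped = clamped[keep],
    reached = reached, n_steps = k_last, params = params,
    start_config = q, start_position = start_pos,
    true_target_id = if (inherits(trajectory, "decoded_trajectory"))
      trajectory$true_target_id else NA_integer_),
    class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("<reach_trial> %d steps (%d gated, %d clamped)%s\n",
              x$n_steps, sum(x$gated), sum(x$clamped),
              if (is.na(x$reached)) "" else
                sprintf(", reached target %d", x$reached)))
  invisible(x)
}

#' @export
summary.reach_trial <- function(object, ...) {
  end <- object$waypoints[nrow(object$waypoints), ]
  cat(sprintf("Shared-control trial: %d steps, alpha = %.2f, beta = %.2f\n",
              object$n_steps, object$params$alpha, object$params$beta))
  cat(sprintf("  start (%.3f, %.3f, %.3f) -> end (%.3f, %.3f, %.3f) m\n",
              object$start_position[1], object$start_position[2],
              object$start_position[3], end[1], end[2], end[3]))
  cat(sprintf("  gated steps: %d, clamped steps: %d, reached: %s\n",
              sum(object$gated), sum(object$clamped),
              ifelse(is.na(object$reached), "none", object$reached)))
  invisible(object)
}

#' Plot a shared-control trial
#'
#' Projections of the waypoint sequence onto the xy and xz planes, with
#' the start marked by a circle.
#'
#' @param x a `reach_trial`.
#' @param targets optional `target_set` to overlay (crosses).
#' @param ... passed to [graphics::plot()].
#' @export
plot.reach_trial <- function(x, targets = NULL, ...) {
  wp <- x$waypoints
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (dims in list(c(1, 2, "x [m]", "y [m]"), c(1, 3, "x [m]", "z [m]"))) {
    i <- as.integer(dims[1]); j <- as.integer(dims[2])
    xs <- wp[, i]; ys <- wp[, j]
    if (!is.null(targets)) {
      xs <- c(xs, targets$positions[, i]); ys <- c(ys, targets$positions[, j])
    }
    graphics::plot(wp[, i], wp[, j], type = "l", xlab = dims[3],
                   ylab = dims[4], xlim = range(xs), ylim = range(ys), ...)
    graphics::points(wp[1, i], wp[1, j], pch = 1, cex = 1.5)
    if (!is.null(targets))
      graphics::points(targets$positions[, i], targets$positions[, j],
                       pch = 4, cex = 1.5)
  }
  invisible(x)
}

#' Write trial waypoints as CSV
#'
#' Columns: `step`, `x`, `y`, `z`, `intended_target_id`, `gated`.
#'
#' @param trial a `reach_trial`.
#' @param path output path.
#' @export
write_waypoints <- function(trial, path) {
  stopifnot(inherits(trial, "reach_trial"))
  wp <- trial$waypoints
  df <- data.frame(step = 0:(nrow(wp) - 1L), x = wp[, 1], y = wp[, 2],
                   z = wp[, 3],
                   intended_target_id = c(NA, trial$intended),
                   gated = c(NA, trial$gated))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
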