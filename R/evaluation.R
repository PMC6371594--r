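#' Shortest distance from a waypoint sequence to a target
#'
#' Minimum Euclidean distance over the listed waypoints (point-wise, not
#' along segments) — the outcome measure of the reaching task.
#'
#' @param waypoints n x 3 matrix of positions (metres).
#' @param target length-3 target position.
#' @return Distance in metres.
#' @export
shortest_distance <- function(waypoints, target) {
  wp <- as.matrix(waypoints)
  stopifnot(nrow(wp) >= 1L, ncol(wp) == 3L, length(target) == 3L)
  min(sqrt(rowSums(sweep(wp, 2, as.numeric(target))^2)))
}

#' Percent decrease of the shortest distance under compensation
#'
#' `100 * (d_raw - d_comp) / d_raw`. Negative values mean the compensated
#' trajectory ended up farther from the target than the raw one. A zero
#' raw baseline leaves the decrease undefined and returns `NA` (flagged
#' with a warning).
#'
#' @param d_raw shortest distance of the raw (uncompensated) trajectory.
#' @param d_comp shortest distance of the compensated trajectory.
#' @return Percent decrease (vectorised); `NA` where `d_raw == 0`.
#' @export
percent_decrease <- function(d_raw, d_comp) {
  stopifnot(all(d_raw >= 0, na.rm = TRUE), all(d_comp >= 0, na.rm = TRUE))
  bad <- !is.na(d_raw) & d_raw == 0
  if (any(bad))
    warning("percent_decrease: zero raw baseline; returning NA for ",
            sum(bad), " case(s)")
  out <- 100 * (d_raw - d_comp) / d_raw
  out[bad] <- NA_real_
  out
}

#' Integrate a decoded velocity stream into a raw trajectory
#'
#' The uncompensated baseline: cumulative sum of the decoded velocities
#' from the start position. `scale = 1` by default (the raw baseline does
#' not include the controller's step gain); pass `scale = 1.5` to apply
#' the same gain the controller uses.
#'
#' @param trajectory a `decoded_trajectory` or n x 3 velocity matrix.
#' @param start length-3 start position.
#' @param scale gain applied to every velocity.
#' @return (n+1) x 3 matrix of waypoints including the start.
#' @export
integrate_raw <- function(trajectory, start, scale = 1) {
  vel <- if (inherits(trajectory, "decoded_trajectory"))
    trajectory$velocities else as.matrix(trajectory)
  start <- as.numeric(start)
  cs <- apply(vel * scale, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = 3)
  rbind(start, sweep(cs, 2, -start), deparse.level = 0)
}

#' Evaluate one trial: raw vs compensated shortest distances
#'
#' Runs the shared controller on the trial, integrates the raw baseline
#' from the same start, and computes shortest distances and percent
#' decreases for the intended (true) target and every nonintended target.
#'
#' @param trajectory a `decoded_trajectory` with a `true_target_id`.
#' @param targets a `target_set`.
#' @param params a `shared_control_params`.
#' @param start_config length-3 starting joint configuration.
#' @param raw_scale gain for the raw baseline (see [integrate_raw()]).
#' @param elbow elbow branch for IK.
#' @return One-row `data.frame`: `direction_label`, `true_target_id`,
#'   `d_raw_intended`, `d_comp_intended`, `decrease_intended`,
#'   `d_raw_nonintended`, `d_comp_nonintended`, `decrease_nonintended`
#'   (the latter three averaged over nonintended targets).
#' @export
evaluate_trial <- function(trajectory, targets, params, start_config,
                           raw_scale = 1, elbow = "up") {
  stopifnot(inherits(trajectory, "decoded_trajectory"))
  dh <- targets$dh
  start_pos <- .fk_pos(normalize_angle(as.numeric(start_config)),
                       dh$a2, dh$a3)
  raw <- integrate_raw(trajectory, start_pos, raw_scale)
  comp <- run_trial(trajectory, targets, params, start_config, elbow)
  iid <- match(trajectory$true_target_id, targets$ids)
  if (is.na(iid))
    stop("evaluate_trial: trial's true target id is not in the target set")
  d_raw <- apply(targets$positions, 1, function(t) shortest_distance(raw, t))
  d_comp <- apply(targets$positions, 1,
                  function(t) shortest_distance(comp$waypoints, t))
  dec <- suppressWarnings(percent_decrease(d_raw, d_comp))
  data.frame(direction_label = trajectory$direction_label,
             true_target_id = trajectory$true_target_id,
             d_raw_intended = d_raw[iid], d_comp_intended = d_comp[iid],
             decrease_intended = dec[iid],
             d_raw_nonintended = mean(d_raw[-iid]),
             d_comp_nonintended = mean(d_comp[-iid]),
             decrease_nonintended = mean(dec[-iid]))
}

#' Evaluate an ensemble of trials at fixed blending parameters
#'
#' @param trials list of `decoded_trajectory` objects.
#' @param targets a `target_set`.
#' @param params a `shared_control_params`.
#' @param start_config length-3 starting joint configuration.
#' @inheritParams evaluate_trial
#' @return `data.frame` with one row per trial (see [evaluate_trial()]),
#'   plus a `trial_id` column.
#' @export
evaluate_trials <- function(trials, targets, params, start_config,
                            raw_scale = 1, elbow = "up") {
  rows <- lapply(trials, evaluate_trial, targets = targets, params = params,
                 start_config = start_config, raw_scale = raw_scale,
                 elbow = elbow)
  out <- do.call(rbind, rows)
  cbind(trial_id = seq_along(trials), out)
}

#' Sweep the blending parameters over a grid
#'
#' Runs every trial through the shared controller for each `(alpha, beta)`
#' cell and records the mean percent decrease of the shortest distance to
#' the intended and nonintended targets, overall and per direction. The
#' raw baseline is computed once per trial (it does not depend on the
#' blending parameters). Trials with an undefined (zero) raw baseline are
#' excluded from the means and counted.
#'
#' @param trials list of `decoded_trajectory` objects.
#' @param targets a `target_set`.
#' @param start_config length-3 starting joint configuration.
#' @param alphas,betas grid values; default the full 0.05-1.00 lattice in
#'   steps of 0.05 (20 x 20 cells).
#' @param step_scale,reach_tolerance controller settings applied to every
#'   cell.
#' @param raw_scale gain for the raw baseline.
#' @param elbow elbow branch for IK.
#' @return Object of class `sweep_result`: list with `alphas`, `betas`,
#'   `mean_intended` and `mean_nonintended` (length(alphas) x
#'   length(betas) matrices), `by_direction` (array alpha x beta x
#'   direction of intended decreases), and `n_excluded`.
#' @export
sweep_shared_control <- function(trials, targets, start_config,
                                 alphas = seq(0.05, 1, by = 0.05),
                                 betas = seq(0.05, 1, by = 0.05),
                                 step_scale = 1.5, reach_tolerance = 0.02,
                                 raw_scale = 1, elbow = "up") {
  stopifnot(length(trials) >= 1L, inherits(targets, "target_set"))
  dh <- targets$dh
  start_pos <- .fk_pos(normalize_angle(as.numeric(start_config)),
                       dh$a2, dh$a3)
  n_tr <- length(trials)
  iidx <- vapply(trials, function(tr) match(tr$true_target_id, targets$ids),
                 0L)
  dirs <- vapply(trials, function(tr) tr$direction_label, 0L)
  dir_levels <- sort(unique(dirs))

  # raw baselines, once per trial
  d_raw <- matrix(NA_real_, n_tr, nrow(targets$positions))
  for (i in seq_len(n_tr)) {
    raw <- integrate_raw(trials[[i]], start_pos, raw_scale)
    d_raw[i, ] <- apply(targets$positions, 1,
                        function(t) shortest_distance(raw, t))
  }
  excluded <- d_raw[cbind(seq_len(n_tr), iidx)] == 0
  n_excl <- sum(excluded)
  if (n_excl > 0)
    message("sweep_shared_control: excluding ", n_excl,
            " trial(s) with zero raw baseline")

  na <- length(alphas); nb <- length(betas)
  mi <- matrix(NA_real_, na, nb, dimnames = list(alphas, betas))
  mn <- matrix(NA_real_, na, nb, dimnames = list(alphas, betas))
  bd <- array(NA_real_, c(na, nb, length(dir_levels)),
              dimnames = list(alphas, betas, dir_levels))
  for (ai in seq_len(na)) {
    for (bi in seq_len(nb)) {
      params <- shared_control_params(alphas[ai], betas[bi],
                                      step_scale = step_scale,
                                      reach_tolerance = reach_tolerance)
      dec_i <- dec_n <- rep(NA_real_, n_tr)
      for (i in seq_len(n_tr)) {
        if (excluded[i]) next
        comp <- run_trial(trials[[i]], targets, params, start_config, elbow)
        d_c <- apply(targets$positions, 1,
                     function(t) shortest_distance(comp$waypoints, t))
        dec <- suppressWarnings(percent_decrease(d_raw[i, ], d_c))
        dec_i[i] <- dec[iidx[i]]
        dec_n[i] <- mean(dec[-iidx[i]], na.rm = TRUE)
      }
      mi[ai, bi] <- mean(dec_i, na.rm = TRUE)
      mn[ai, bi] <- mean(dec_n, na.rm = TRUE)
      for (di in seq_along(dir_levels))
        bd[ai, bi, di] <- mean(dec_i[dirs == dir_levels[di]], na.rm = TRUE)
    }
  }
  structure(list(alphas = alphas, betas = betas, mean_intended = mi,
                 mean_nonintended = mn, by_direction = bd,
                 n_excluded = n_excl),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d x %d (alpha x beta) grid\n",
              length(x$alphas), length(x$betas)))
  best <- which(x$mean_intended == max(x$mean_intended), arr.ind = TRUE)[1, ]
  cat(sprintf(
    "  best mean intended decrease %.2f%% at alpha = %.2f, beta = %.2f\n",
    max(x$mean_intended), x$alphas[best[1]], x$betas[best[2]]))
  if (x$n_excluded > 0)
    cat("  excluded trials:", x$n_excluded, "\n")
  invisible(x)
}

#' Plot a blending-parameter sweep surface
#'
#' Heatmap of the mean percent decrease of the shortest distance to the
#' intended (default) or nonintended targets over the (alpha, beta) grid.
#'
#' @param x a `sweep_result`.
#' @param which `"intended"` or `"nonintended"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_result <- function(x, which = c("intended", "nonintended"),
                              ...) {
  which <- match.arg(which)
  z <- if (which == "intended") x$mean_intended else x$mean_nonintended
  graphics::image(x$alphas, x$betas, z, xlab = expression(alpha),
                  ylab = expression(beta),
                  main = paste("Mean decrease,", which, "target (%)"),
                  col = grDevices::hcl.colors(24, "viridis"), ...)
  graphics::contour(x$alphas, x$betas, z, add = TRUE)
  invisible(x)
}

#' One-tailed two-sample t-test: intended vs nonintended decreases
#'
#' Tests whether the percent decrease to the intended target exceeds that
#' to the nonintended targets, using a pooled-variance two-sample t-test
#' by default (Welch's correction behind `welch = TRUE`), one-tailed with
#' alternative "intended greater".
#'
#' @param decreases_intended,decreases_nonintended numeric samples
#'   (n >= 2 each; `NA`s dropped).
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   one.
#' @return List with `statistic`, `df`, `p.value`, `method`, and
#'   `degenerate` (`TRUE` when both samples have zero variance, in which
#'   case the statistic is `NA`).
#' @export
intended_vs_nonintended_test <- function(decreases_intended,
                                         decreases_nonintended,
                                         welch = FALSE) {
  x <- decreases_intended[!is.na(decreases_intended)]
  y <- decreases_nonintended[!is.na(decreases_nonintended)]
  if (length(x) < 2L || length(y) < 2L)
    stop("intended_vs_nonintended_test: both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                method = "degenerate (zero variance)", degenerate = TRUE))
  tt <- stats::t.test(x, y, alternative = "greater", var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, method = tt$method, degenerate = FALSE)
}

#' Chance level of the target-selection task
#'
#' The success rate expected from random target selection among the
#' candidates: `100 / n_targets` percent.
#'
#' @param n_targets number of candidate targets (integer >= 1).
#' @return Chance level in percent.
#' @examples
#' chance_level(2)  # 50
#' chance_level(4)  # 25
#' @export
chance_level <- function(n_targets) {
  if (!is.numeric(n_targets) || length(n_targets) != 1L ||
      n_targets < 1 || n_targets != round(n_targets))
    stop("chance_level: n_targets must be an integer >= 1")
  100 / n_targets
}
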