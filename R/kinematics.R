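#' Denavit-Hartenberg table of the 3-DOF positioning chain
#'
#' The arm's positioning subchain is an anthropomorphic 3-DOF arm: a
#' vertical shoulder rotation (theta1), then shoulder elevation (theta2)
#' and elbow (theta3) in the arm plane. Link parameters: `a = (0, a2, a3)`,
#' `alpha = (pi/2, 0, 0)`, `d = (0, 0, 0)`, with upper-arm and forearm
#' lengths `a2 = 0.41` m and `a3 = 0.44` m by default.
#'
#' @param a2,a3 link lengths in metres (> 0).
#' @return Object of class `dh_table`.
#' @export
dh_table <- function(a2 = 0.41, a3 = 0.44) {
  stopifnot(is.numeric(a2), is.numeric(a3), a2 > 0, a3 > 0)
  structure(list(a = c(0, a2, a3), alpha = c(pi / 2, 0, 0), d = c(0, 0, 0),
                 a2 = a2, a3 = a3),
            class = "dh_table")
}

#' @export
print.dh_table <- function(x, ...) {
  cat("<dh_table> 3-DOF anthropomorphic arm\n")
  print(data.frame(link = 1:3, a = x$a, alpha = x$alpha, d = x$d,
                   theta = c("theta1", "theta2", "theta3")))
  invisible(x)
}

#' Forward kinematics of the 3-DOF arm
#'
#' End-effector pose in frame 0 (origin at the shoulder). The position is
#' `(c1 (a2 c2 + a3 c23), s1 (a2 c2 + a3 c23), a2 s2 + a3 s23)` where
#' `ci = cos(theta_i)`, `si = sin(theta_i)` and `c23 = cos(theta2 + theta3)`.
#'
#' @param q length-3 numeric of joint angles `(theta1, theta2, theta3)` in
#'   radians.
#' @param dh a `dh_table`.
#' @return Object of class `ee_pose`: list with `position` (length-3,
#'   metres) and `rotation` (3 x 3 orthogonal matrix).
#' @examples
#' arm_forward(c(0, 0, 0))$position       # fully extended: (0.85, 0, 0)
#' arm_forward(c(0, pi / 2, 0))$position  # straight up:    (0, 0, 0.85)
#' @export
arm_forward <- function(q, dh = dh_table()) {
  stopifnot(is.numeric(q), length(q) == 3L, all(is.finite(q)))
  c1 <- cos(q[1]); s1 <- sin(q[1])
  c2 <- cos(q[2]); s2 <- sin(q[2])
  c23 <- cos(q[2] + q[3]); s23 <- sin(q[2] + q[3])
  r <- dh$a2 * c2 + dh$a3 * c23
  structure(list(
    position = c(c1 * r, s1 * r, dh$a2 * s2 + dh$a3 * s23),
    rotation = rbind(c(c1 * c23, -c1 * s23, s1),
                     c(s1 * c23, -s1 * s23, -c1),
                     c(s23, c23, 0))),
    class = "ee_pose")
}

#' @export
print.ee_pose <- function(x, ...) {
  cat(sprintf("<ee_pose> position (%.4f, %.4f, %.4f) m\n",
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

# fast position-only FK used inside the control loop
.fk_pos <- function(q, a2, a3) {
  r <- a2 * cos(q[2]) + a3 * cos(q[2] + q[3])
  c(cos(q[1]) * r, sin(q[1]) * r, a2 * sin(q[2]) + a3 * sin(q[2] + q[3]))
}

#' Inverse kinematics of the 3-DOF arm
#'
#' Closed-form solution: the elbow angle follows from the law of cosines,
#' `c3 = (|p|^2 - a2^2 - a3^2) / (2 a2 a3)` with `s3 = +/- sqrt(1 - c3^2)`
#' chosen by the elbow branch; then
#' `theta2 = atan2((a2 + a3 c3) pz - a3 s3 r, (a2 + a3 c3) r + a3 s3 pz)`
#' with `r = sqrt(px^2 + py^2)`, and `theta1 = atan2(py, px)`. Returned
#' angles are normalized to `(-pi, pi]`.
#'
#' At a vertical reach (`px = py = 0`) the shoulder rotation is undefined;
#' by convention `theta1 = 0` is returned with a warning.
#'
#' @param position length-3 target position in frame 0, metres. Must lie in
#'   the reachable annulus `|a2 - a3| <= |p| <= a2 + a3` (within 1e-9 m).
#' @param dh a `dh_table`.
#' @param elbow `"up"` (default, `s3 >= 0`) or `"down"` (`s3 <= 0`).
#' @return Length-3 numeric of joint angles.
#' @export
arm_inverse <- function(position, dh = dh_table(), elbow = c("up", "down")) {
  elbow <- match.arg(elbow)
  p <- as.numeric(position)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  a2 <- dh$a2; a3 <- dh$a3
  n2 <- sum(p^2); n <- sqrt(n2)
  tol <- 1e-9
  if (n > a2 + a3 + tol || n < abs(a2 - a3) - tol)
    stop(sprintf(paste0("arm_inverse: position at radius %.6f m is outside ",
                        "the reachable annulus [%.3f, %.3f] m"),
                 n, abs(a2 - a3), a2 + a3))
  c3 <- (n2 - a2^2 - a3^2) / (2 * a2 * a3)
  c3 <- min(max(c3, -1), 1)               # clamp fp overshoot at the boundary
  s3 <- sqrt(max(1 - c3^2, 0))
  if (elbow == "down") s3 <- -s3
  r <- sqrt(p[1]^2 + p[2]^2)
  if (r == 0) {
    if (n > 0)
      warning("arm_inverse: vertical reach, theta1 undefined; returning 0")
    th1 <- 0
  } else th1 <- atan2(p[2], p[1])
  th2 <- atan2((a2 + a3 * c3) * p[3] - a3 * s3 * r,
               (a2 + a3 * c3) * r + a3 * s3 * p[3])
  th3 <- atan2(s3, c3)
  normalize_angle(c(th1, th2, th3))
}

#' Normalize angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles wrapped into `(-pi, pi]`.
#' @export
normalize_angle <- function(theta) {
  out <- theta %% (2 * pi)
  out[out > pi] <- out[out > pi] - 2 * pi
  out
}

#' Offset between the robot base origin and frame 0
#'
#' The robot's coordinate origin sits 0.2 m along both x and z from the
#' frame-0 origin (the centre of joint 1). `robot_to_frame0()` converts a
#' robot-frame position (e.g. a localized target) to frame-0 coordinates
#' for kinematics and control; `frame0_to_robot()` is the inverse.
#'
#' @param p length-3 position in metres (or n x 3 matrix).
#' @param offset length-3 offset of the robot origin from frame 0, metres.
#' @return Converted position(s).
#' @export
robot_to_frame0 <- function(p, offset = c(0.2, 0, 0.2)) {
  if (is.matrix(p)) return(sweep(p, 2, -offset))
  as.numeric(p) + offset
}

#' @rdname robot_to_frame0
#' @export
frame0_to_robot <- function(p, offset = c(0.2, 0, 0.2)) {
  if (is.matrix(p)) return(sweep(p, 2, offset))
  as.numeric(p) - offset
}
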