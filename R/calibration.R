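#' Camera calibration model
#'
#' Bundles the three calibrations that take a detected pixel cluster to a
#' metric position in the Kinect frame: the affine RGB-pixel to depth-pixel
#' map `B`, the linear depth-index to distance law, and the per-axis linear
#' pixel-to-metre coefficients (which scale with distance).
#'
#' @param B 3 x 2 matrix: `[x y 1] %*% B` maps an RGB pixel to a depth
#'   pixel. Rows are the x-coefficient, y-coefficient and intercept.
#' @param depth_slope,depth_intercept linear depth law
#'   `distance = depth_slope * index + depth_intercept` (metres);
#'   `depth_slope` must be positive.
#' @param x_coeff,y_coeff length-2 numeric `(c1, c2)` so that a pixel offset
#'   `p` from the optical centre at distance `d` maps to
#'   `(c1 * d + c2) * p` metres along the corresponding axis.
#' @return An object of class `calibration_model`.
#' @seealso [default_calibration()] for the rig's measured values.
#' @export
calibration_model <- function(B, depth_slope, depth_intercept,
                              x_coeff, y_coeff) {
  B <- matrix(as.numeric(B), 3, 2)
  stopifnot(all(is.finite(B)), is.numeric(depth_slope), depth_slope > 0,
            is.finite(depth_intercept),
            length(x_coeff) == 2L, length(y_coeff) == 2L,
            all(is.finite(c(x_coeff, y_coeff))))
  structure(list(B = B, depth_slope = as.numeric(depth_slope),
                 depth_intercept = as.numeric(depth_intercept),
                 x_coeff = as.numeric(x_coeff),
                 y_coeff = as.numeric(y_coeff)),
            class = "calibration_model")
}

#' Default calibration of the training rig
#'
#' The calibration measured on the physical rig: the RGB-to-depth pixel
#' map fitted from 165 ball correspondences, the depth-index law
#' `distance = 61.5 * index + 0.1046` m, and the distance-dependent
#' pixel-to-metre coefficients. These defaults make the full pipeline
#' runnable without any camera hardware; [fit_pixel_mapping()] refits `B`
#' from user-supplied correspondences.
#'
#' @return A `calibration_model`.
#' @export
default_calibration <- function() {
  calibration_model(
    B = rbind(c(1.17332, 0.000815),
              c(-0.01963, 1.12255),
              c(-34.6797, -20.0941)),
    depth_slope = 61.5, depth_intercept = 0.1046,
    x_coeff = c(0.001937, 0.0001662),
    y_coeff = c(0.002072, -0.000227))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n  B (RGB px -> depth px):\n")
  print(round(x$B, 5))
  cat(sprintf("  distance = %.4g * index + %.4g m\n",
              x$depth_slope, x$depth_intercept))
  cat(sprintf("  X = (%.6g d + %.6g) px,  Y = (%.6g d + %.6g) px\n",
              x$x_coeff[1], x$x_coeff[2], x$y_coeff[1], x$y_coeff[2]))
  invisible(x)
}

#' Fit the RGB-to-depth pixel mapping by least squares
#'
#' Solves `D = [A 1] %*% B` for the 3 x 2 affine map `B` from paired pixel
#' coordinates of the same objects seen in the RGB and depth images,
#' i.e. `B = (X'X)^-1 X'D` with `X = [A 1]`.
#'
#' @param rgb_coords n x 2 matrix of RGB-image pixel coordinates (n >= 3).
#' @param depth_coords n x 2 matrix of matching depth-image coordinates.
#' @return 3 x 2 matrix `B` (rows: x-coefficients, y-coefficients,
#'   intercepts).
#' @export
fit_pixel_mapping <- function(rgb_coords, depth_coords) {
  A <- as.matrix(rgb_coords); D <- as.matrix(depth_coords)
  stopifnot(ncol(A) == 2L, ncol(D) == 2L, nrow(A) == nrow(D))
  if (nrow(A) < 3L)
    stop("fit_pixel_mapping: need at least 3 point correspondences")
  X <- cbind(A, 1)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("fit_pixel_mapping: design matrix [A 1] is rank deficient; ",
         "points must not be collinear")
  B <- qr.coef(qx, D)
  dimnames(B) <- NULL
  B
}

#' Map an RGB pixel to depth-image coordinates
#'
#' @param pixel length-2 `(x, y)` pixel, or an n x 2 matrix of pixels.
#' @param B 3 x 2 affine map (see [fit_pixel_mapping()]); defaults to the
#'   rig calibration.
#' @return Mapped coordinates in the same shape as `pixel`.
#' @export
map_rgb_to_depth <- function(pixel, B = default_calibration()$B) {
  stopifnot(all(is.finite(B)), all(dim(B) == c(3, 2)))
  if (is.matrix(pixel)) return(cbind(pixel, 1) %*% B)
  drop(c(pixel, 1) %*% B)
}

#' Convert a depth index to metric distance
#'
#' @param depth_index numeric depth index (the raw one-channel depth-image
#'   value), vectorised.
#' @param model a `calibration_model`.
#' @return Distance in metres.
#' @export
depth_to_distance <- function(depth_index, model = default_calibration()) {
  stopifnot(all(is.finite(depth_index)))
  model$depth_slope * depth_index + model$depth_intercept
}

#' Convert pixel offsets to metric XY at a known distance
#'
#' Pixel offsets are measured from the optical centre of the RGB image;
#' the metres-per-pixel scale grows linearly with distance.
#'
#' @param pixel_offset length-2 `(x, y)` offset in pixels from the optical
#'   centre.
#' @param distance distance along the optical axis in metres (> 0).
#' @param model a `calibration_model`.
#' @return Length-2 numeric `(X, Y)` in metres.
#' @export
pixel_to_metric_xy <- function(pixel_offset, distance,
                               model = default_calibration()) {
  if (!is.numeric(distance) || any(distance <= 0))
    stop("pixel_to_metric_xy: distance must be positive")
  c(X = (model$x_coeff[1] * distance + model$x_coeff[2]) * pixel_offset[1],
    Y = (model$y_coeff[1] * distance + model$y_coeff[2]) * pixel_offset[2])
}

#' Metric point with a frame label
#'
#' @param x,y,z coordinates in metres (or `x` a length-3 vector).
#' @param frame `"kinect"` or `"robot"`.
#' @return Length-3 numeric of class `metric_point` with a `frame`
#'   attribute.
#' @export
metric_point <- function(x, y = NULL, z = NULL,
                         frame = c("kinect", "robot")) {
  frame <- match.arg(frame)
  p <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  structure(stats::setNames(p, c("x", "y", "z")),
            class = "metric_point", frame = frame)
}

#' @export
print.metric_point <- function(x, ...) {
  cat(sprintf("<metric_point %s> (%.4f, %.4f, %.4f) m\n",
              attr(x, "frame"), x[1], x[2], x[3]))
  invisible(x)
}

#' Rigid transform from the Kinect frame to the robot frame
#'
#' The camera and arm are bolted to opposite ends of the rig, so a fixed
#' homogeneous transform relates their frames. The default is the rig's
#' mounting geometry: rotation `[[0,0,-1],[1,0,0],[0,-1,0]]` and
#' translation `(1.24, 0, 0.05)` m.
#'
#' @param rotation 3 x 3 rotation matrix (orthogonal, determinant +1).
#' @param translation length-3 translation in metres.
#' @return Object of class `frame_transform` with elements `R`,
#'   `translation`, and the 4 x 4 homogeneous matrix `T`.
#' @export
frame_transform <- function(rotation = rbind(c(0, 0, -1),
                                             c(1, 0, 0),
                                             c(0, -1, 0)),
                            translation = c(1.24, 0, 0.05)) {
  R <- matrix(as.numeric(rotation), 3, 3)
  t <- as.numeric(translation)
  stopifnot(length(t) == 3L, all(is.finite(R)), all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("frame_transform: rotation must be orthogonal with determinant +1")
  T <- rbind(cbind(R, t), c(0, 0, 0, 1))
  structure(list(R = R, translation = t, T = T), class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat("<frame_transform> T =\n"); print(round(x$T, 4)); invisible(x)
}

#' Transform a Kinect-frame point into the robot frame
#'
#' @param point a `metric_point` with frame `"kinect"`.
#' @param transform a `frame_transform`; defaults to the rig geometry.
#' @return A `metric_point` in the robot frame.
#' @export
kinect_to_robot <- function(point, transform = frame_transform()) {
  if (!inherits(point, "metric_point") || attr(point, "frame") != "kinect")
    stop("kinect_to_robot: input must be a metric_point in the kinect frame")
  metric_point(drop(transform$R %*% as.numeric(point)) +
                 transform$translation, frame = "robot")
}

#' Localize detected clusters to metric robot-frame positions
#'
#' For each cluster: map the RGB centroid to depth-image coordinates via
#' `B`, bilinearly sample the depth-index grid there, convert the index to
#' distance, convert the RGB pixel offset from the optical centre to metric
#' XY, assemble the Kinect-frame point `(X, Y, distance)`, and apply the
#' Kinect-to-robot transform.
#'
#' @param clusters list of `pixel_cluster` objects (see [detect_targets()]).
#' @param depth_image numeric matrix of depth indices with the same
#'   dimensions as the RGB image.
#' @param model a `calibration_model`.
#' @param transform a `frame_transform`.
#' @param optical_center length-2 `(x, y)` pixel of the optical axis;
#'   default `(W/2, H/2)`.
#' @return `data.frame` with columns `target_id`, `x`, `y`, `z` (metres)
#'   and `frame` (`"robot"`); zero rows for an empty cluster list.
#' @export
localize_targets <- function(clusters, depth_image,
                             model = default_calibration(),
                             transform = frame_transform(),
                             optical_center = NULL) {
  stopifnot(is.matrix(depth_image), all(is.finite(depth_image)))
  h <- nrow(depth_image); w <- ncol(depth_image)
  if (is.null(optical_center)) optical_center <- c(w / 2, h / 2)
  out <- data.frame(target_id = integer(), x = numeric(), y = numeric(),
                    z = numeric(), frame = character())
  for (i in seq_along(clusters)) {
    cen <- clusters[[i]]$centroid
    dp <- map_rgb_to_depth(as.numeric(cen), model$B)
    if (dp[1] < 0 || dp[1] > w - 1 || dp[2] < 0 || dp[2] > h - 1)
      stop(sprintf(paste0("localize_targets: cluster %d maps to depth ",
                          "pixel (%.1f, %.1f), outside the %dx%d image"),
                   i, dp[1], dp[2], w, h))
    idx <- .bilinear(depth_image, dp[1], dp[2])
    dist <- depth_to_distance(idx, model)
    xy <- pixel_to_metric_xy(as.numeric(cen) - optical_center, dist, model)
    p <- kinect_to_robot(metric_point(xy[1], xy[2], dist, frame = "kinect"),
                         transform)
    out <- rbind(out, data.frame(target_id = i, x = p[1], y = p[2],
                                 z = p[3], frame = "robot"))
  }
  out
}

# bilinear sample of grid at 0-based (x, y) = (column, row)
.bilinear <- function(grid, x, y) {
  h <- nrow(grid); w <- ncol(grid)
  x0 <- min(max(floor(x), 0), w - 2); y0 <- min(max(floor(y), 0), h - 2)
  fx <- x - x0; fy <- y - y0
  g00 <- grid[y0 + 1, x0 + 1]; g01 <- grid[y0 + 1, x0 + 2]
  g10 <- grid[y0 + 2, x0 + 1]; g11 <- grid[y0 + 2, x0 + 2]
  (1 - fy) * ((1 - fx) * g00 + fx * g01) + fy * ((1 - fx) * g10 + fx * g11)
}

#' Read or write a calibration model as JSON
#'
#' The serialized form uses the field names `B`, `depth_slope`,
#' `depth_intercept`, `x_coeff`, `y_coeff`.
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `read_calibration()` returns a `calibration_model`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(B = model$B, depth_slope = model$depth_slope,
         depth_intercept = model$depth_intercept,
         x_coeff = model$x_coeff, y_coeff = model$y_coeff),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- if (is.matrix(j$B)) j$B else matrix(unlist(j$B), 3, 2, byrow = TRUE)
  calibration_model(B = B,
                    depth_slope = j$depth_slope,
                    depth_intercept = j$depth_intercept,
                    x_coeff = j$x_coeff, y_coeff = j$y_coeff)
}
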