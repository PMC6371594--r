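test_that("pixel mapping recovers a noiseless affine map exactly", {
  set.seed(42)
  A <- cbind(runif(20, 0, 640), runif(20, 0, 480))
  B_true <- rbind(c(1.2, 0.01), c(-0.02, 1.1), c(-30, -18))
  D <- cbind(A, 1) %*% B_true
  expect_lt(max(abs(fit_pixel_mapping(A, D) - B_true)), 1e-9)
  # identity correspondence -> identity map
  expect_lt(max(abs(fit_pixel_mapping(A, A) -
                      rbind(c(1, 0), c(0, 1), c(0, 0)))), 1e-9)
  # invariant to the ordering of the correspondences
  p <- sample(nrow(A))
  expect_equal(fit_pixel_mapping(A[p, ], D[p, ]), fit_pixel_mapping(A, D))
  # degenerate geometry is refused
  expect_error(fit_pixel_mapping(cbind(1:5, 2 * (1:5)),
                                 cbind(1:5, 1:5)), "rank deficient")
  expect_error(fit_pixel_mapping(A[1:2, ], D[1:2, ]), "at least 3")
})

test_that("fit residuals under seeded pixel noise sit at the noise scale", {
  set.seed(165)
  A <- cbind(runif(165, 0, 640), runif(165, 0, 480))
  B_true <- default_calibration()$B
  D <- cbind(A, 1) %*% B_true + matrix(rnorm(2 * 165, sd = 3), ncol = 2)
  B_hat <- fit_pixel_mapping(A, D)
  resid <- D - cbind(A, 1) %*% B_hat
  rmse <- sqrt(colMeans(resid^2))
  expect_true(all(rmse > 2 & rmse < 4))
})

test_that("the rig's RGB-to-depth map reproduces its printed action", {
  B <- default_calibration()$B
  expect_equal(map_rgb_to_depth(c(0, 0), B), c(-34.6797, -20.0941))
  expect_equal(map_rgb_to_depth(c(1, 0), B),
               c(1.17332 - 34.6797, 0.000815 - 20.0941))
  # identity map leaves pixels unchanged; matrix input is vectorised
  I3 <- rbind(c(1, 0), c(0, 1), c(0, 0))
  expect_equal(map_rgb_to_depth(c(123.4, 56.7), I3), c(123.4, 56.7))
  px <- cbind(c(0, 1), c(0, 0))
  expect_equal(map_rgb_to_depth(px, B)[1, ], c(-34.6797, -20.0941))
})

test_that("depth law is the calibrated line and strictly increasing", {
  expect_equal(depth_to_distance(0), 0.1046)
  expect_equal(depth_to_distance(0.01), 0.7196)
  expect_equal(depth_to_distance(0.02), 1.3346)
  idx <- seq(0, 0.05, length.out = 50)
  expect_true(all(diff(depth_to_distance(idx)) > 0))
})

test_that("pixel offsets convert to metric XY with the distance-scaled law", {
  expect_equal(unname(pixel_to_metric_xy(c(0, 0), 1.7)), c(0, 0))
  expect_equal(unname(pixel_to_metric_xy(c(100, 0), 1)[1]), 0.21032)
  expect_equal(unname(pixel_to_metric_xy(c(0, 100), 1)[2]), 0.18450)
  expect_error(pixel_to_metric_xy(c(10, 10), 0), "positive")
})

test_that("Kinect-to-robot transform matches the rig geometry", {
  o <- kinect_to_robot(metric_point(0, 0, 0, frame = "kinect"))
  expect_equal(as.numeric(o), c(1.24, 0, 0.05))
  expect_equal(attr(o, "frame"), "robot")
  expect_equal(as.numeric(kinect_to_robot(metric_point(0, 0, 1, "kinect"))),
               c(0.24, 0, 0.05))
  expect_equal(as.numeric(kinect_to_robot(metric_point(1, 0, 0, "kinect"))),
               c(1.24, 1, 0.05))
  # rigid: pairwise distances preserved
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    ra <- kinect_to_robot(metric_point(a, frame = "kinect"))
    rb <- kinect_to_robot(metric_point(b, frame = "kinect"))
    expect_equal(sqrt(sum((ra - rb)^2)), sqrt(sum((a - b)^2)))
  }
  expect_error(kinect_to_robot(metric_point(1, 2, 3, frame = "robot")),
               "kinect frame")
  expect_error(frame_transform(rotation = diag(3) * 2), "orthogonal")
})

test_that("localization inverts the forward camera model to numeric precision", {
  # known Kinect-frame target, identity pixel map, uniform exact depth
  p_kinect <- c(0.1, 0.2, 1.0)
  model <- calibration_model(B = rbind(c(1, 0), c(0, 1), c(0, 0)),
                             depth_slope = 61.5, depth_intercept = 0.1046,
                             x_coeff = c(0.001937, 0.0001662),
                             y_coeff = c(0.002072, -0.000227))
  w <- 640; h <- 480
  mx <- model$x_coeff[1] * 1.0 + model$x_coeff[2]
  my <- model$y_coeff[1] * 1.0 + model$y_coeff[2]
  centroid <- c(w / 2 + p_kinect[1] / mx, h / 2 + p_kinect[2] / my)
  cluster <- structure(list(pixels = matrix(centroid, 1),
                            centroid = centroid, std_x = 0, std_y = 0,
                            n_pixels = 1L), class = "pixel_cluster")
  depth <- matrix((1.0 - model$depth_intercept) / model$depth_slope, h, w)
  loc <- localize_targets(list(cluster), depth, model)
  tf <- frame_transform()
  expected <- drop(tf$R %*% p_kinect) + tf$translation
  expect_lt(max(abs(as.numeric(loc[1, c("x", "y", "z")]) - expected)), 1e-6)
  expect_equal(loc$frame, "robot")
  # empty input -> empty table, not an error
  expect_equal(nrow(localize_targets(list(), depth, model)), 0)
  # a centroid mapping outside the depth image is an out-of-view error
  far <- cluster; far$centroid <- c(10000, 10)
  expect_error(localize_targets(list(far), depth, model), "outside")
})

test_that("inter-target distance survives centroid noise at the cm scale", {
  set.seed(31)
  model <- default_calibration()
  spec <- scene_spec(n_targets = 2, seed = 3,
                     target_positions = rbind(c(-0.15, 0, 1.0),
                                              c(0.15, 0, 1.0)))
  sc <- render_scene(spec, model)
  errs <- replicate(20, {
    cl <- detect_targets(sc$rgb)
    # sigma = 1 px centroid jitter
    cl <- lapply(cl, function(c_i) {
      c_i$centroid <- c_i$centroid + rnorm(2, sd = 1); c_i
    })
    loc <- localize_targets(cl, sc$depth, model)
    d <- dist(as.matrix(loc[, c("x", "y", "z")]))[1]
    abs(d - 0.30)
  })
  expect_lt(mean(errs), 0.03)
})

test_that("calibration JSON serialization round-trips", {
  model <- default_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(model, path)
  back <- read_calibration(path)
  expect_equal(back$B, model$B)
  expect_equal(back$depth_slope, model$depth_slope)
  expect_equal(back$x_coeff, model$x_coeff)
  j <- jsonlite::read_json(path)
  expect_named(j, c("B", "depth_slope", "depth_intercept",
                    "x_coeff", "y_coeff"))
})
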