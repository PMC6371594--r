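#' Detect green targets in an RGB image
#'
#' Full detection pipeline for green target objects on a plain background:
#' colour-ratio segmentation ([segment_green()]), 3x3 erosion denoising
#' ([denoise()]), and divisive hierarchical clustering
#' ([divisive_cluster()]). The number of targets is not assumed in advance;
#' clusters are split until their pixel spread falls below `std_threshold`
#' on both image axes.
#'
#' @param image RGB image: an `H x W x 3` numeric array with channel values
#'   in `[0, 255]` (see [read_rgb_image()]), `H, W >= 3`.
#' @param threshold green-ratio threshold in (0, 1); a pixel is foreground
#'   when `G / (R + G + B) > threshold`. Default 0.5.
#' @param std_threshold pixel-spread threshold (pixels) at which a cluster
#'   is split in two. Default 20.
#' @return A list of `pixel_cluster` objects, sorted by centroid x then y.
#'   Each carries `pixels` (n x 2 matrix of 0-based `(x, y)` = (column, row)
#'   coordinates), `centroid`, `std_x`, `std_y`, and `n_pixels`.
#' @examples
#' img <- array(120, dim = c(60, 80, 3))
#' img[20:30, 10:20, ] <- rep(c(30, 200, 30), each = 11 * 11)
#' detect_targets(img)
#' @export
detect_targets <- function(image, threshold = 0.5, std_threshold = 20) {
  divisive_cluster(denoise(segment_green(image, threshold)), std_threshold)
}

#' Segment green pixels by colour ratio
#'
#' A pixel is classified as target (1) when its green fraction
#' `G / (R + G + B)` exceeds `threshold`. A pure black pixel (0, 0, 0) has an
#' undefined ratio and is defined to be background.
#'
#' @inheritParams detect_targets
#' @return Binary matrix (`H x W`, values 0/1).
#' @export
segment_green <- function(image, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  .check_rgb(image)
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  ratio <- ifelse(s == 0, 0, image[, , 2] / s)
  (ratio > threshold) * 1
}

#' Erode a binary image with a 3x3 structuring element
#'
#' Noise filtering for segmented masks: an output pixel is 1 only when the
#' 3x3 mean over its neighbourhood equals exactly 1, i.e. all nine
#' neighbours are foreground (morphological erosion). The 3x3 window is
#' undefined on the image border, so border pixels are set to 0.
#'
#' @param binary binary matrix (values 0/1), at least 3x3.
#' @return Binary matrix of the same dimensions.
#' @export
denoise <- function(binary) {
  .check_binary(binary)
  h <- nrow(binary); w <- ncol(binary)
  if (h < 3 || w < 3)
    stop("denoise: image must be at least 3x3, got ", h, "x", w)
  acc <- matrix(0, h - 2, w - 2)
  for (di in 0:2)
    for (dj in 0:2)
      acc <- acc + binary[(1 + di):(h - 2 + di), (1 + dj):(w - 2 + dj)]
  out <- matrix(0, h, w)
  out[2:(h - 1), 2:(w - 1)] <- (acc == 9) * 1
  out
}

#' Divisive hierarchical clustering of foreground pixels
#'
#' Starts from a single cluster holding every foreground pixel. Any cluster
#' whose x- or y-axis population standard deviation is `>= std_threshold`
#' is split into two sub-clusters; splitting repeats until every cluster is
#' below the threshold on both axes. This needs no prior knowledge of the
#' number of targets, unlike fixed-k centroid clustering.
#'
#' The two-way split is a deterministic 2-means on the pixel coordinates:
#' centroids are initialised at the two extreme pixels along the axis of
#' larger spread and Lloyd iterations run to convergence (centroid movement
#' below 1e-6 px, at most 100 iterations); assignment ties go to the first
#' centroid.
#'
#' @param binary binary matrix (0/1 foreground mask).
#' @param std_threshold split threshold in pixels (> 0), default 20.
#' @param max_depth recursion guard on the split depth; exceeded only on
#'   pathological inputs. Default 16.
#' @return List of `pixel_cluster` objects (possibly empty), sorted by
#'   centroid x then y; the clusters partition the foreground pixels and
#'   every returned cluster has `std_x < std_threshold` and
#'   `std_y < std_threshold`.
#' @export
divisive_cluster <- function(binary, std_threshold = 20, max_depth = 16) {
  .check_binary(binary)
  stopifnot(is.numeric(std_threshold), length(std_threshold) == 1L,
            std_threshold > 0)
  idx <- which(binary == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  # x = column, y = row, 0-based; which() order fixes a deterministic input
  px <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)

  final <- list()
  queue <- list(list(px = px, depth = 0L))
  while (length(queue) > 0L) {
    node <- queue[[1L]]; queue <- queue[-1L]
    sds <- .pop_sd(node$px)
    if (sds[1] < std_threshold && sds[2] < std_threshold) {
      final[[length(final) + 1L]] <- .new_cluster(node$px, sds)
    } else {
      if (node$depth >= max_depth)
        stop("divisive_cluster: maximum split depth ", max_depth,
             " exceeded (", nrow(node$px), " pixels, std_x = ",
             signif(sds[1], 4), ", std_y = ", signif(sds[2], 4), ")")
      parts <- .split_two_means(node$px, sds)
      queue <- c(queue, list(list(px = parts[[1]], depth = node$depth + 1L),
                             list(px = parts[[2]], depth = node$depth + 1L)))
    }
  }
  cx <- vapply(final, function(cl) cl$centroid[1], 0)
  cy <- vapply(final, function(cl) cl$centroid[2], 0)
  final[order(cx, cy)]
}

# population standard deviation (divide by n) of pixel x and y
.pop_sd <- function(px) {
  n <- nrow(px)
  c(sqrt(sum((px[, 1] - mean(px[, 1]))^2) / n),
    sqrt(sum((px[, 2] - mean(px[, 2]))^2) / n))
}

.new_cluster <- function(px, sds = .pop_sd(px)) {
  structure(list(pixels = px,
                 centroid = c(x = mean(px[, 1]), y = mean(px[, 2])),
                 std_x = sds[1], std_y = sds[2],
                 n_pixels = nrow(px)),
            class = "pixel_cluster")
}

#' @export
print.pixel_cluster <- function(x, ...) {
  cat(sprintf(
    "<pixel_cluster> %d px, centroid (%.2f, %.2f), std (%.2f, %.2f)\n",
    x$n_pixels, x$centroid[1], x$centroid[2], x$std_x, x$std_y))
  invisible(x)
}

# deterministic 2-means split; init = extreme pixels along the wider axis
.split_two_means <- function(px, sds, tol = 1e-6, max_iter = 100L) {
  axis <- if (sds[2] > sds[1]) 2L else 1L   # tie -> x axis
  c1 <- px[which.min(px[, axis]), , drop = TRUE]
  c2 <- px[which.max(px[, axis]), , drop = TRUE]
  a <- NULL
  for (iter in seq_len(max_iter)) {
    d1 <- (px[, 1] - c1[1])^2 + (px[, 2] - c1[2])^2
    d2 <- (px[, 1] - c2[1])^2 + (px[, 2] - c2[2])^2
    a <- d1 <= d2                            # tie -> first centroid
    if (all(a) || !any(a)) {
      # degenerate assignment: fall back to a median cut along the axis
      a <- px[, axis] <= stats::median(px[, axis])
      if (all(a) || !any(a)) a <- seq_len(nrow(px)) <= nrow(px) / 2
      break
    }
    n1 <- c(mean(px[a, 1]), mean(px[a, 2]))
    n2 <- c(mean(px[!a, 1]), mean(px[!a, 2]))
    moved <- max(abs(c(n1 - c1, n2 - c2)))
    c1 <- n1; c2 <- n2
    if (moved < tol) break
  }
  list(px[a, , drop = FALSE], px[!a, , drop = FALSE])
}

.check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  d <- dim(image)
  if (d[1] < 3 || d[2] < 3)
    stop("RGB image must be at least 3x3")
  if (min(image) < 0 || max(image) > 255)
    stop("RGB channel values must lie in [0, 255]")
  invisible(TRUE)
}

.check_binary <- function(binary) {
  if (!is.matrix(binary) || !all(binary %in% c(0, 1)))
    stop("expected a binary (0/1) matrix")
  invisible(TRUE)
}

#' Read an RGB image from a PNG file
#'
#' Returns the `H x W x 3` array convention used throughout the package,
#' with channel values scaled to `[0, 255]`. An alpha channel, if present,
#' is dropped.
#'
#' @param path PNG file path.
#' @return `H x W x 3` numeric array.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write a binary mask as a PNG file
#'
#' @param binary binary matrix.
#' @param path output path.
#' @export
write_mask <- function(binary, path) {
  .check_binary(binary)
  png::writePNG(binary, path)
  invisible(path)
}

#' Tabulate detected clusters
#'
#' @param clusters list of `pixel_cluster` objects.
#' @return `data.frame` with columns `cluster_id`, `centroid_x`,
#'   `centroid_y`, `n_pixels`, `std_x`, `std_y`.
#' @export
clusters_to_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), n_pixels = integer(),
                      std_x = numeric(), std_y = numeric()))
  data.frame(
    cluster_id = seq_along(clusters),
    centroid_x = vapply(clusters, function(cl) cl$centroid[[1]], 0),
    centroid_y = vapply(clusters, function(cl) cl$centroid[[2]], 0),
    n_pixels   = vapply(clusters, function(cl) cl$n_pixels, 0L),
    std_x      = vapply(clusters, function(cl) cl$std_x, 0),
    std_y      = vapply(clusters, function(cl) cl$std_y, 0))
}
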