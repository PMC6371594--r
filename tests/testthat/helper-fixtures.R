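# Shared fixtures and independent oracles, built in code.

# binary image with square blobs of half-width `half` at 0-based (x, y)
# centers
make_blob_image <- function(h, w, centers, half = 5) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    rows <- (cy - half):(cy + half) + 1
    cols <- (cx - half):(cx + half) + 1
    img[rows, cols] <- 1
  }
  img
}

# brute-force 3x3 erosion oracle: per-pixel all-ones test, borders zero
erode_oracle <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  out <- matrix(0, h, w)
  for (i in 2:(h - 1))
    for (j in 2:(w - 1))
      out[i, j] <- as.numeric(all(binary[(i - 1):(i + 1),
                                         (j - 1):(j + 1)] == 1))
  out
}

# connected-component labelling oracle (4-connectivity flood fill)
cc_label <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (binary[i0, j0] == 1 && lab[i0, j0] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i0, j0))
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        i <- p[1]; j <- p[2]
        if (i < 1 || i > h || j < 1 || j > w) next
        if (binary[i, j] != 1 || lab[i, j] != 0L) next
        lab[i, j] <- nxt
        stack <- c(stack, list(c(i - 1, j), c(i + 1, j),
                               c(i, j - 1), c(i, j + 1)))
      }
    }
  }
  lab
}

# canonical partition signature: sorted list of sorted pixel-key vectors
partition_signature <- function(groups) {
  keys <- lapply(groups, function(g) sort(g[, 1] * 1e5 + g[, 2]))
  unname(keys[order(vapply(keys, min, 0))])
}

# small reaching geometry shared across control/evaluation tests
test_layout <- function() default_reach_layout()

# reduced synthetic ensemble for fast tests
small_ensemble <- function(seed = 11, trials_per_direction = 5,
                           n_steps = 40, angular_noise_sd = 0.6) {
  lay <- test_layout()
  spec <- trajectory_spec(trials_per_direction = trials_per_direction,
                          n_steps = n_steps,
                          angular_noise_sd = angular_noise_sd, seed = seed)
  list(layout = lay,
       trials = generate_trials(spec, lay$targets, lay$start_position))
}
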