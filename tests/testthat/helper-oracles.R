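# Independent oracles used across the test files.

# Brute-force Otsu oracle: evaluates the between-class variance of the
# split {f < theta} vs {f >= theta} directly from the pixel values for
# every candidate threshold, returning the lowest argmax. Independent of
# the histogram/cumsum implementation under test.
brute_force_threshold <- function(pixels, candidates = 1:255) {
  v <- as.vector(pixels)
  n <- length(v)
  best_theta <- NA_real_
  best_var <- -1
  for (theta in candidates) {
    bg <- v[v < theta]
    fg <- v[v >= theta]
    if (length(bg) == 0L || length(fg) == 0L) s2 <- 0
    else {
      w0 <- length(bg) / n
      s2 <- w0 * (1 - w0) * (mean(bg) - mean(fg))^2
    }
    if (s2 > best_var + 1e-12) {        # strictly greater: lowest tie wins
      best_var <- s2
      best_theta <- theta
    }
  }
  list(theta = best_theta, between_class_variance = best_var)
}

# A small mono image from a plain matrix.
as_mono <- function(m, bit_depth = 8L, um_per_pixel = 1) {
  cyanocount::mono_image(m, bit_depth, um_per_pixel)
}

# Fixed confusion matrix from TP/TN/FP/FN for a binary problem with the
# positive class first.
cm_from_counts <- function(tp, tn, fp, fn, classes = c("pos", "neg")) {
  truth <- c(rep(classes[1], tp + fn), rep(classes[2], tn + fp))
  pred <- c(rep(classes[1], tp), rep(classes[2], fn),
            rep(classes[2], tn), rep(classes[1], fp))
  cyanocount::confusion_matrix(truth, pred, classes)
}

# Default run configuration matching the generator's calibration.
test_config <- function(...) {
  cyanocount::run_config(um_per_pixel = 0.645, ...)
}

# Small single-cell calibration scenes for a species.
calibration_images <- function(species = c("C_A", "C_M"), n_images = 2,
                               seed = 100) {
  species <- match.arg(species)
  lapply(seq_len(n_images), function(i) {
    spec <- if (species == "C_A") {
      cyanocount::scene_spec(
        image_size = c(500, 600), counts = c(C_A = 30),
        filament = list(cells_mean = 1, cells_sd = 0, cell_length_um = 6.83,
                        width_um = 5.0, curvature = 0, overlap_frac = 0.1),
        seed = seed + i)
    } else {
      cyanocount::scene_spec(image_size = c(500, 600),
                             counts = c(C_M = 30), seed = seed + i)
    }
    cyanocount::generate_scene(spec)$image
  })
}
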