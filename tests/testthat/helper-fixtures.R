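# Shared fixtures, all generated in code.

tiny_phantom <- function(n = 8, seed = 1L, n_classes = 6, ...) {
  generate_phantom_dataset(phantom_config(n_samples = n, seed = seed,
                                          n_classes = n_classes, ...))
}

# A deterministic 4-channel input batch with mild structure.
random_batch <- function(h = 16, w = 16, c = 4, n = 3, seed = 7L) {
  withr::with_seed(seed, array(runif(h * w * c * n), c(h, w, c, n)))
}

random_labels <- function(n = 3, k = 6, seed = 8L) {
  withr::with_seed(seed, matrix(rbinom(n * k, 1, 0.4), n, k))
}

# Direct Gaussian-kernel-sum heatmap oracle (independent of the package's
# vectorized renderer).
heatmap_oracle <- function(gaze, width, height, sigma,
                           duration_weighted = TRUE) {
  d <- matrix(0, height, width)
  for (r in seq_len(height)) {
    for (co in seq_len(width)) {
      px <- co - 0.5; py <- r - 0.5
      for (i in seq_len(nrow(gaze))) {
        w <- if (duration_weighted) gaze$duration[i] else 1
        d[r, co] <- d[r, co] +
          w * exp(-((px - gaze$x[i])^2 + (py - gaze$y[i])^2) / (2 * sigma^2))
      }
    }
  }
  if (max(d) > 0) d <- d / max(d)
  d
}
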