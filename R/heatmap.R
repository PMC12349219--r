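#' Render an expert fixation heatmap from gaze records
#'
#' Sums an isotropic Gaussian kernel at every fixation location (optionally
#' weighted by fixation duration, the attention-bearing quantity) and
#' max-normalizes the result to \[0,1\], so the heatmap channel shares the
#' grayscale image's range for early fusion. An empty gaze table yields an
#' all-zero density. The RGB rendering uses the package's fixed blue-to-red
#' colormap (blue = low fixation density, red = highest concentration).
#'
#' @param gaze data frame with columns `x`, `y` (pixels, 0-based, origin
#'   top-left), `duration` (ms); e.g. from [read_gaze_csv()] or a phantom
#'   sample.
#' @param width,height output grid size in pixels.
#' @param sigma Gaussian kernel bandwidth in pixels. Default
#'   `min(width, height) / 25`, a one-degree-of-visual-angle surrogate common
#'   in saliency mapping.
#' @param duration_weighted weight each kernel by the fixation's duration
#'   (default TRUE).
#' @return a `fixation_heatmap`: list with `density` (`height x width` matrix,
#'   max 1 or all zero) and `rgb` (`height x width x 3` array in \[0,1\]).
#' @examples
#' hm <- render_fixation_heatmap(data.frame(x = 32, y = 32, duration = 250),
#'                               64, 64)
#' max(hm$density)
#' @export
render_fixation_heatmap <- function(gaze, width, height,
                                    sigma = min(width, height) / 25,
                                    duration_weighted = TRUE) {
  if (sigma <= 0) stopf("sigma must be positive, got %s", format(sigma))
  if (width < 1 || height < 1) stopf("width and height must be >= 1")
  density <- matrix(0, height, width)
  if (nrow(gaze) > 0) {
    if (any(!is.finite(gaze$x)) || any(!is.finite(gaze$y)))
      stopf("gaze coordinates must be finite")
    far <- gaze$x < -3 * sigma | gaze$x > width + 3 * sigma |
      gaze$y < -3 * sigma | gaze$y > height + 3 * sigma
    if (any(far))
      warnf("%d fixation(s) more than 3*sigma outside the image bounds; %s",
            sum(far), "they still contribute via the kernel tail")
    xs <- seq_len(width) - 0.5
    ys <- seq_len(height) - 0.5
    w <- if (duration_weighted) gaze$duration else rep(1, nrow(gaze))
    for (i in seq_len(nrow(gaze))) {
      kx <- exp(-((xs - gaze$x[i])^2) / (2 * sigma^2))
      ky <- exp(-((ys - gaze$y[i])^2) / (2 * sigma^2))
      density <- density + w[i] * (ky %o% kx)
    }
    m <- max(density)
    if (m > 0) density <- density / m
  }
  structure(list(density = density, rgb = colorize_density(density)),
            class = "fixation_heatmap")
}

# Fixed blue -> teal -> amber -> red lookup table. Control points are chosen
# with strictly increasing channel sums so overall brightness, like hue, is
# monotone in density — low densities read as dark blue, the peak as bright
# red.
heat_lut <- function() {
  list(pos = c(0, 0.35, 0.7, 1),
       col = rbind(c(0.05, 0.10, 0.55),
                   c(0.10, 0.50, 0.60),
                   c(0.70, 0.55, 0.10),
                   c(1.00, 0.30, 0.20)))
}

#' Colorize a density grid with the package's blue-to-red colormap
#'
#' Deterministic per-pixel lookup: equal densities always map to equal colors,
#' and every color channel is a piecewise-linear function of density.
#'
#' @param density matrix with values in \[0,1\]; values outside are clipped
#'   with a warning.
#' @return `nrow x ncol x 3` RGB array in \[0,1\].
#' @export
colorize_density <- function(density) {
  if (any(density < 0 | density > 1)) {
    warnf("density values outside [0,1] were clipped")
    density <- clamp01(density)
  }
  lut <- heat_lut()
  out <- array(0, c(nrow(density), ncol(density), 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(stats::approx(lut$pos, lut$col[, ch],
                                        xout = as.vector(density))$y,
                          nrow(density), ncol(density))
  out
}

#' Preprocess an image for the network
#'
#' Deterministic geometry in evaluation mode: bilinear resize of the short
#' side to `out_size` followed by a center crop. In training mode a seeded
#' Gaussian blur (slight, against overfitting) and brightness/contrast jitter
#' are applied on top.
#'
#' Apply the same call (same mode and seed) to the image and its fixation
#' heatmap channels to keep the two modalities spatially registered.
#'
#' @param image grayscale matrix in \[0,1\] (rows = y).
#' @param train_mode apply seeded augmentation (default FALSE).
#' @param aug_seed integer seed for the augmentation draws.
#' @param out_size output side length, pixels (default 224).
#' @param blur_sigma Gaussian blur bandwidth in pixels (train mode).
#' @param jitter maximum relative brightness/contrast perturbation
#'   (train mode; default 0.1).
#' @return `out_size x out_size` matrix in \[0,1\].
#' @export
preprocess_image <- function(image, train_mode = FALSE, aug_seed = 0L,
                             out_size = 224, blur_sigma = 1,
                             jitter = 0.1) {
  if (length(image) == 0 || is.null(dim(image)))
    stopf("image must be a non-empty matrix")
  h <- nrow(image); w <- ncol(image)
  s <- out_size / min(h, w)
  out <- resize_grid(image, round(h * s), round(w * s))
  # center crop to out_size x out_size
  r0 <- floor((nrow(out) - out_size) / 2)
  c0 <- floor((ncol(out) - out_size) / 2)
  out <- out[r0 + seq_len(out_size), c0 + seq_len(out_size), drop = FALSE]
  if (train_mode) {
    out <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(out)),
                                               sigma = blur_sigma)))
    jit <- with_seed(aug_seed, runif(2, -jitter, jitter))
    out <- (1 + jit[1]) * (out - 0.5) + 0.5 + jit[2] # contrast then brightness
  }
  clamp01(out)
}
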