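#' Configuration for the synthetic phantom generator
#'
#' Builds and validates the parameter set controlling phantom radiograph
#' generation: how many samples, image geometry, per-class lesion prevalence,
#' lesion contrast and size, and the statistical structure of the simulated
#' expert gaze (how many fixations, what fraction of them target lesions, and
#' how tightly they scatter around the target).
#'
#' Each class is assigned a characteristic zone of the image (a ceiling grid
#' over the frame; with a single class the zone is the whole image), loosely
#' mimicking the anatomically localized presentation of radiographic findings.
#' Lesions are additive Gaussian-profile blobs; the recorded ellipse ROI is the
#' blob's 2-sigma contour, so ROI masks are exact by construction.
#'
#' @param n_samples number of phantom samples to generate.
#' @param image_size side length of the square image, pixels (>= 16).
#' @param n_classes number of abnormality classes (default 6, the size of the
#'   label set used for chest-radiograph findings).
#' @param class_prevalence per-class probability of a positive label, recycled
#'   to `n_classes`.
#' @param lesion_intensity additive grayscale contrast of a lesion blob, in
#'   \[0,1\].
#' @param lesion_radius_range range (pixels) for the major semi-axis of the
#'   2-sigma lesion ellipse.
#' @param fixation_count_range range for the number of fixations per image.
#' @param on_lesion_fraction probability that a fixation targets a lesion
#'   center (when the image has lesions) rather than being a uniform
#'   distractor.
#' @param fixation_scatter standard deviation (pixels) of fixation placement
#'   around its target.
#' @param seed integer seed; identical configs give bitwise-identical datasets.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_samples = 100,
                           image_size = 64,
                           n_classes = 6,
                           class_prevalence = 0.3,
                           lesion_intensity = 0.3,
                           lesion_radius_range = c(6, 12),
                           fixation_count_range = c(20, 50),
                           on_lesion_fraction = 0.7,
                           fixation_scatter = 3,
                           seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              image_size = as.integer(image_size),
              n_classes = as.integer(n_classes),
              class_prevalence = rep_len(as.numeric(class_prevalence), n_classes),
              lesion_intensity = as.numeric(lesion_intensity),
              lesion_radius_range = as.numeric(lesion_radius_range),
              fixation_count_range = as.numeric(fixation_count_range),
              on_lesion_fraction = as.numeric(on_lesion_fraction),
              fixation_scatter = as.numeric(fixation_scatter),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) stopf("invalid `%s`: %s", field, msg)
  chk(length(cfg$n_samples) == 1 && !is.na(cfg$n_samples) && cfg$n_samples >= 0,
      "n_samples", "must be a single nonnegative integer")
  chk(length(cfg$image_size) == 1 && !is.na(cfg$image_size) && cfg$image_size >= 16,
      "image_size", "must be >= 16")
  chk(cfg$n_classes >= 1, "n_classes", "must be >= 1")
  chk(all(cfg$class_prevalence >= 0 & cfg$class_prevalence <= 1),
      "class_prevalence", "probabilities must lie in [0, 1]")
  chk(cfg$lesion_intensity >= 0 && cfg$lesion_intensity <= 1,
      "lesion_intensity", "must lie in [0, 1]")
  chk(length(cfg$lesion_radius_range) == 2 &&
        all(cfg$lesion_radius_range > 0) &&
        diff(cfg$lesion_radius_range) >= 0 &&
        max(cfg$lesion_radius_range) < cfg$image_size / 2,
      "lesion_radius_range",
      "must be an increasing positive pair with max < image_size/2")
  chk(length(cfg$fixation_count_range) == 2 &&
        all(cfg$fixation_count_range >= 0) &&
        diff(cfg$fixation_count_range) >= 0,
      "fixation_count_range", "must be a nondecreasing nonnegative pair")
  chk(cfg$on_lesion_fraction >= 0 && cfg$on_lesion_fraction <= 1,
      "on_lesion_fraction", "must lie in [0, 1]")
  chk(cfg$fixation_scatter >= 0, "fixation_scatter", "must be >= 0")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

# Characteristic zone of class k: cell k of an nr x nc grid over the image
# (row-major). Returns c(x0, x1, y0, y1) in pixel coordinates.
class_zone <- function(k, n_classes, image_size) {
  nr <- max(1L, floor(sqrt(n_classes)))
  nc <- ceiling(n_classes / nr)
  row <- (k - 1) %/% nc
  col <- (k - 1) %% nc
  c(x0 = col * image_size / nc, x1 = (col + 1) * image_size / nc,
    y0 = row * image_size / nr, y1 = (row + 1) * image_size / nr)
}

# Smooth low-frequency background: bilinear ramp between random corner
# intensities plus Gaussian pixel noise (sd 0.05).
phantom_background <- function(size) {
  corners <- runif(4, 0.3, 0.42) # tl, tr, bl, br
  u <- (seq_len(size) - 0.5) / size
  top <- corners[1] + (corners[2] - corners[1]) * u
  bot <- corners[3] + (corners[4] - corners[3]) * u
  bg <- outer(1 - u, top) + outer(u, bot) # rows = y
  clamp01(bg + matrix(rnorm(size * size, 0, 0.05), size, size))
}

phantom_lesion <- function(cfg, k) {
  size <- cfg$image_size
  a <- runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
  b <- a * runif(1, 0.7, 1)
  theta <- runif(1, 0, 180)
  m <- a + 0.5 # keep the 2-sigma ellipse fully inside the frame
  z <- class_zone(k, cfg$n_classes, size)
  cx <- runif(1, max(z["x0"], m), min(z["x1"], size - m))
  cy <- runif(1, max(z["y0"], m), min(z["y1"], size - m))
  list(class = k, cx = unname(cx), cy = unname(cy), a = a, b = b,
       theta_deg = theta)
}

# Additive lesion whose 2-sigma contour is the ROI ellipse. Each class has a
# characteristic texture (cycled for n_classes > 6), standing in for the
# distinct radiological appearance of different findings:
#   1 solid bright blob          4 speckled blob
#   2 annular (ring) opacity     5 horizontally striated opacity
#   3 dark (lucent) blob         6 vertically striated opacity
add_blob <- function(img, roi, intensity) {
  size <- nrow(img)
  x <- matrix(rep(seq_len(size) - 0.5, each = size), size, size) # cols
  y <- matrix(rep(seq_len(size) - 0.5, size), size, size)        # rows
  th <- roi$theta_deg * pi / 180
  dx <- x - roi$cx; dy <- y - roi$cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  q <- (u / (roi$a / 2))^2 + (v / (roi$b / 2))^2
  env <- exp(-q / 2)
  pattern <- (roi$class - 1) %% 6 + 1
  lesion <- switch(pattern,
    intensity * env,
    intensity * exp(-(sqrt(q) - 1.2)^2 / (2 * 0.18)),
    -0.9 * intensity * env,
    intensity * env * matrix(runif(size * size, 0.2, 1.8), size, size),
    intensity * env * (0.55 + 0.65 * sin(2 * pi * y / 4)),
    intensity * env * (0.55 + 0.65 * sin(2 * pi * x / 4)))
  clamp01(img + lesion)
}

phantom_gaze <- function(cfg, rois) {
  n <- round(runif(1, cfg$fixation_count_range[1], cfg$fixation_count_range[2]))
  size <- cfg$image_size
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      duration = numeric(0), t_start = numeric(0)))
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    if (length(rois) > 0 && runif(1) < cfg$on_lesion_fraction) {
      r <- rois[[sample.int(length(rois), 1)]]
      x[i] <- min(max(r$cx + rnorm(1, 0, cfg$fixation_scatter), 0), size - 1e-6)
      y[i] <- min(max(r$cy + rnorm(1, 0, cfg$fixation_scatter), 0), size - 1e-6)
    } else {
      x[i] <- runif(1, 0, size)
      y[i] <- runif(1, 0, size)
    }
  }
  # Durations: log-normal with median 250 ms (no published distribution for
  # this setting; see the methods vignette). Start times accumulate duration
  # plus a short inter-fixation gap.
  duration <- rlnorm(n, meanlog = log(250), sdlog = 0.4)
  gaps <- runif(n, 20, 80)
  t_start <- cumsum(c(0, head(duration + gaps, -1)))
  data.frame(x = x, y = y, duration = duration, t_start = t_start)
}

#' Generate a seeded synthetic phantom dataset
#'
#' Produces `n_samples` phantom radiographs with planted lesion blobs, their
#' exact ellipse ROIs, multilabel targets, and expert-like fixation tables in
#' which a tunable fraction of fixations concentrates on lesions. The entire
#' dataset is a deterministic function of the config (including its seed).
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom_dataset`: a list of samples, each with
#'   `image` (matrix in \[0,1\], rows = y), `labels` (0/1 integer vector),
#'   `rois` (list of ellipses: class, cx, cy, a, b, theta_deg) and `gaze`
#'   (data frame x, y, duration, t_start; ms and pixels). The config is kept
#'   in `attr(, "config")`.
#' @examples
#' ds <- generate_phantom_dataset(phantom_config(n_samples = 2, seed = 7))
#' dim(ds[[1]]$image)
#' @export
generate_phantom_dataset <- function(config) {
  validate_phantom_config(config)
  samples <- with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      labels <- rbinom(config$n_classes, 1, config$class_prevalence)
      rois <- lapply(which(labels == 1), function(k) phantom_lesion(config, k))
      img <- phantom_background(config$image_size)
      for (r in rois) img <- add_blob(img, r, config$lesion_intensity)
      list(image = img, labels = as.integer(labels), rois = rois,
           gaze = phantom_gaze(config, rois))
    })
  })
  structure(samples, class = "phantom_dataset", config = config)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("phantom_dataset: %d samples, %dx%d px, %d classes\n",
              length(x), cfg$image_size, cfg$image_size, cfg$n_classes))
  invisible(x)
}

#' Rasterize an ellipse ROI to a binary mask
#'
#' A pixel belongs to the mask iff its center satisfies the rotated-ellipse
#' inequality `(u/a)^2 + (v/b)^2 <= 1`, where (u, v) are the pixel-center
#' offsets from the ellipse center rotated into the ellipse frame. Pixel
#' centers sit at integer + 0.5 in 0-based image coordinates.
#'
#' @param roi list with `cx`, `cy` (center, pixels), `a`, `b` (semi-axes,
#'   pixels, > 0) and `theta_deg` (rotation, degrees).
#' @param width,height mask dimensions in pixels.
#' @return a logical `height x width` matrix (rows = y).
#' @examples
#' m <- ellipse_to_mask(list(cx = 8.5, cy = 8.5, a = 0.5, b = 0.5,
#'                           theta_deg = 0), 16, 16)
#' sum(m) # exactly one pixel
#' @export
ellipse_to_mask <- function(roi, width, height) {
  if (is.null(roi$a) || is.null(roi$b) || roi$a <= 0 || roi$b <= 0)
    stopf("ellipse semi-axes must be positive (got a=%s, b=%s)",
          format(roi$a), format(roi$b))
  x <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  y <- matrix(rep(seq_len(height) - 0.5, width), height, width)
  th <- (roi$theta_deg %||% 0) * pi / 180
  dx <- x - roi$cx; dy <- y - roi$cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / roi$a)^2 + (v / roi$b)^2 <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom dataset to disk as PNG images and CSV tables
#'
#' Emits one grayscale PNG per sample plus per-image gaze CSVs
#' (`x_px, y_px, duration_ms, t_start_ms`), a single ellipse table
#' (`image_id, class, cx, cy, a, b, theta_deg`), a label table, and a manifest
#' CSV indexing all files.
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(dataset, "config")
  ids <- sprintf("sample_%04d", seq_along(dataset))
  rois <- list(); labels <- list()
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    png::writePNG(s$image, file.path(dir, paste0(ids[i], ".png")))
    gz <- s$gaze
    names(gz) <- c("x_px", "y_px", "duration_ms", "t_start_ms")
    write.csv(gz, file.path(dir, paste0(ids[i], "_gaze.csv")),
              row.names = FALSE)
    if (length(s$rois) > 0)
      rois[[length(rois) + 1]] <- data.frame(
        image_id = ids[i],
        class = vapply(s$rois, `[[`, numeric(1), "class"),
        cx = vapply(s$rois, `[[`, numeric(1), "cx"),
        cy = vapply(s$rois, `[[`, numeric(1), "cy"),
        a = vapply(s$rois, `[[`, numeric(1), "a"),
        b = vapply(s$rois, `[[`, numeric(1), "b"),
        theta_deg = vapply(s$rois, `[[`, numeric(1), "theta_deg"))
    labels[[i]] <- data.frame(image_id = ids[i],
                              t(setNames(s$labels,
                                         paste0("class_", seq_len(cfg$n_classes)))))
  }
  roi_df <- if (length(rois)) do.call(rbind, rois) else
    data.frame(image_id = character(0), class = numeric(0), cx = numeric(0),
               cy = numeric(0), a = numeric(0), b = numeric(0),
               theta_deg = numeric(0))
  write.csv(roi_df, file.path(dir, "ellipses.csv"), row.names = FALSE)
  write.csv(do.call(rbind, labels), file.path(dir, "labels.csv"),
            row.names = FALSE)
  manifest <- data.frame(image_id = ids,
                         image = paste0(ids, ".png"),
                         gaze = paste0(ids, "_gaze.csv"))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a gaze fixation table
#'
#' Accepts the package's CSV layout (`x_px, y_px, duration_ms, t_start_ms`) or
#' any table whose first four columns are x, y, duration and start time.
#'
#' @param path CSV file path.
#' @return data frame with columns `x`, `y`, `duration`, `t_start`.
#' @export
read_gaze_csv <- function(path) {
  g <- read.csv(path)
  if (ncol(g) < 4) stopf("gaze table needs >= 4 columns, got %d", ncol(g))
  g <- g[, 1:4]
  names(g) <- c("x", "y", "duration", "t_start")
  g
}
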