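#' Striped-noise specification
#'
#' Describes the test-time corruption protocol for fixation heatmaps: a
#' seeded random subset of full-width (or full-height) stripes of a given
#' thickness is overwritten, so that the affected-pixel fraction matches
#' `level` up to one stripe quantum.
#'
#' @param level fraction of affected pixels in \[0,1\] (the radiograph
#'   experiments use 0.10 and 0.50).
#' @param stripe_thickness stripe thickness in pixels (>= 1).
#' @param orientation `"horizontal"` (default) or `"vertical"`.
#' @param fill `"zero"` erases the fixation evidence in the stripe (default);
#'   `"shuffle"` permutes the stripe's own pixel values.
#' @param seed integer seed selecting the stripes.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(level, stripe_thickness = 2,
                       orientation = c("horizontal", "vertical"),
                       fill = c("zero", "shuffle"), seed = 1L) {
  orientation <- match.arg(orientation)
  fill <- match.arg(fill)
  if (level < 0 || level > 1) stopf("level must lie in [0,1], got %s",
                                    format(level))
  if (stripe_thickness < 1) stopf("stripe_thickness must be >= 1")
  structure(list(level = level, stripe_thickness = as.integer(stripe_thickness),
                 orientation = orientation, fill = fill,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Logical matrix marking the pixels covered by the seeded stripe selection.
stripe_mask <- function(height, width, spec) {
  extent <- if (spec$orientation == "horizontal") height else width
  t <- spec$stripe_thickness
  if (t > extent)
    stopf("stripe_thickness %d exceeds image extent %d", t, extent)
  n_bands <- ceiling(extent / t)
  k <- min(n_bands, round(spec$level * extent / t))
  mask <- matrix(FALSE, height, width)
  if (k > 0) {
    bands <- with_seed(spec$seed, sample.int(n_bands, k))
    for (b in bands) {
      lines <- ((b - 1) * t + 1):min(b * t, extent)
      if (spec$orientation == "horizontal") mask[lines, ] <- TRUE
      else mask[, lines] <- TRUE
    }
  }
  mask
}

#' Inject striped noise into a fixation heatmap
#'
#' Overwrites a seeded random subset of stripes in the heatmap's density
#' according to the fill policy and re-derives the RGB rendering, preserving
#' the invariant that the colors are a deterministic function of the density.
#' `level = 0` returns the input unchanged.
#'
#' @param heatmap a `fixation_heatmap`.
#' @param spec a [noise_spec()].
#' @return the corrupted `fixation_heatmap`; the logical matrix of affected
#'   pixels is attached as `attr(, "affected")`.
#' @export
inject_striped_noise <- function(heatmap, spec) {
  if (spec$level == 0) {
    attr(heatmap, "affected") <- matrix(FALSE, nrow(heatmap$density),
                                        ncol(heatmap$density))
    return(heatmap)
  }
  d <- heatmap$density
  mask <- stripe_mask(nrow(d), ncol(d), spec)
  if (spec$fill == "zero") {
    d[mask] <- 0
  } else {
    d[mask] <- with_seed(spec$seed + 1L, sample(d[mask]))
  }
  out <- structure(list(density = d, rgb = colorize_density(d)),
                   class = "fixation_heatmap")
  attr(out, "affected") <- mask
  out
}

# Corrupt the heatmap channels (2:4) of a 4-channel input batch; the image
# channel is left untouched. Stripes are re-drawn per sample with a seed
# derived from spec$seed and the sample index. Zero fill writes the colormap's
# zero-density color so stripes look like evidence-free heatmap regions.
noise_batch <- function(x, spec) {
  if (spec$level == 0 || dim(x)[3] < 4) return(x)
  zero_rgb <- colorize_density(matrix(0, 1, 1))[1, 1, ]
  for (i in seq_len(dim(x)[4])) {
    si <- spec
    si$seed <- spec$seed + i
    mask <- stripe_mask(dim(x)[1], dim(x)[2], si)
    for (ch in 1:3) {
      plane <- x[, , 1 + ch, i]
      if (spec$fill == "zero") plane[mask] <- zero_rgb[ch]
      else plane[mask] <- with_seed(si$seed + 1L, sample(plane[mask]))
      x[, , 1 + ch, i] <- plane
    }
  }
  x
}

#' Sweep classification AUC across fixation-noise levels
#'
#' Corrupts only the heatmap channels of every test input at each noise level
#' (the image channel is bit-identical before and after) and reports the
#' macro-averaged one-vs-rest AUC. Level 0 is always included as the clean
#' reference; for a single-channel (image-only) model the corruption is a
#' no-op.
#'
#' @param model a trained `gf_model`.
#' @param x test inputs `H x W x C x N`.
#' @param y test labels `N x K`.
#' @param levels noise levels to test; 0 is prepended if absent.
#' @param spec_template a [noise_spec()] supplying thickness, orientation,
#'   fill and seed (its level is overridden per sweep point).
#' @return data frame with columns `level` and `macro_auc`.
#' @export
run_noise_sweep <- function(model, x, y, levels = c(0, 0.1, 0.5),
                            spec_template = noise_spec(0)) {
  x <- as_batch(x)
  if (!0 %in% levels) levels <- c(0, levels)
  levels <- sort(unique(levels))
  aucs <- vapply(levels, function(lv) {
    sp <- spec_template
    sp$level <- lv
    probs <- model_predict(model, noise_batch(x, sp))
    macro_auc(probs, y)
  }, numeric(1))
  data.frame(level = levels, macro_auc = aucs)
}
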