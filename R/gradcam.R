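#' Capture activations and class-score gradients at a backbone layer
#'
#' Runs one forward pass in evaluation mode and one analytic backward pass
#' from the pre-sigmoid logit of the target class down to the requested
#' convolutional layer, recording the layer's post-activation feature maps
#' `A^k` and the gradients `dy^c / dA^k_ij`. Model weights are not mutated.
#'
#' @param model a `gf_model`.
#' @param x a single input sample, `H x W x C` (or `H x W x C x 1`).
#' @param target_class class index in `1..n_classes`.
#' @param target_layer `"conv2"` (default, the last convolution stage) or
#'   `"conv1"`; for the late-fusion model, `"conv2_img"` / `"conv2_hm"`.
#' @return an `activation_capture`: list with `activations` and `gradients`
#'   (both `h x w x K`), `Z` (number of spatial locations), `layer`,
#'   `target_class`.
#' @export
capture_activations <- function(model, x, target_class,
                                target_layer = "conv2") {
  x <- as_batch(x)
  if (dim(x)[4] != 1) stopf("capture_activations expects a single sample")
  k <- model$config$n_classes
  if (target_class < 1 || target_class > k)
    stopf("target_class %d outside 1..%d", target_class, k)
  fwd <- model_forward(model, x, train_mode = FALSE, cache = TRUE)
  ch <- fwd$cache
  d_feat <- model$config$width[2]
  if (model$type == "late_fusion") {
    branch <- switch(target_layer,
                     conv2 = , conv2_img = list(bb = ch$bi, off = 0),
                     conv2_hm = list(bb = ch$bh, off = d_feat),
                     stopf("unknown target_layer '%s' for late_fusion model",
                           target_layer))
    bb <- branch$bb
    df <- model$params$head$W[branch$off + seq_len(d_feat), target_class]
    layer <- "conv2"
  } else {
    if (!target_layer %in% c("conv1", "conv2"))
      stopf("unknown target_layer '%s' (use \"conv1\" or \"conv2\")",
            target_layer)
    bb <- ch$bb
    df <- model$params$head$W[, target_class]
    layer <- target_layer
  }
  # back through global max pooling: gradient routed to each feature map's
  # peak location
  d2 <- dim(bb$a2)
  dA2 <- array(0, d2)
  dA2[bb$amax + (seq_along(bb$amax) - 1) * d2[1] * d2[2]] <- df
  if (layer == "conv2") {
    A <- bb$a2; G <- dA2
  } else {
    bp <- if (model$type == "late_fusion") NULL else model$params$backbone
    dz2 <- dA2 * (bb$z2 > 0)
    dp1 <- conv2d_bwd_cpp(bb$p1, bp$conv2$W, dz2, 1L)$dx
    G <- avgpool2_bwd_cpp(dp1)
    A <- bb$a1
  }
  da <- dim(A)
  structure(list(activations = array(A, da[1:3]),
                 gradients = array(G, da[1:3]),
                 Z = da[1] * da[2],
                 layer = target_layer, target_class = target_class),
            class = "activation_capture")
}

#' Gradient-weighted class activation map from a capture
#'
#' Pools each feature map's gradients over space,
#' `alpha_k = (1/Z) sum_ij dy^c/dA^k_ij`, and forms
#' `ReLU(sum_k alpha_k A^k)`: the ReLU retains only the regions whose
#' activation increases the class score.
#'
#' @param capture an `activation_capture`.
#' @return a `gradcam_map`: list with `raw` (nonnegative `h x w` matrix at
#'   the hooked layer's resolution), `weights` (`alpha_k`), `layer`,
#'   `target_class`.
#' @export
gradcam <- function(capture) {
  if (is.null(capture$Z) || capture$Z == 0) stopf("empty capture (Z = 0)")
  A <- capture$activations
  G <- capture$gradients
  alpha <- apply(G, 3, mean)
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (kk in seq_along(alpha)) raw <- raw + alpha[kk] * A[, , kk]
  raw <- relu(raw)
  stopifnot(all(raw >= 0))
  structure(list(raw = raw, weights = alpha, layer = capture$layer,
                 target_class = capture$target_class),
            class = "gradcam_map")
}

#' Post-process a class activation map for display
#'
#' Min-max normalizes the raw map to \[0,1\] (a constant map — including
#' all-zero — becomes all-zero, with a warning when it was constant
#' positive), optionally flips it vertically (a dataset-specific orientation
#' fix, off by default), bilinearly upscales it to the requested output size,
#' and renders it through the package colormap.
#'
#' @param map a `gradcam_map`.
#' @param out_width,out_height output size in pixels.
#' @param flip_vertical flip rows before upscaling (default FALSE).
#' @return the `gradcam_map` with a `display` field: list with `norm`
#'   (`out_height x out_width` matrix in \[0,1\]) and `rgb` (RGB array).
#' @export
postprocess_cam <- function(map, out_width, out_height,
                            flip_vertical = FALSE) {
  if (out_width < 1 || out_height < 1)
    stopf("output dims must be positive, got %dx%d", out_width, out_height)
  raw <- map$raw
  if (length(raw) == 0) stopf("empty raw map")
  rng <- range(raw)
  if (diff(rng) == 0) {
    if (rng[1] > 0)
      warnf("constant positive activation map normalized to all-zero")
    norm <- matrix(0, nrow(raw), ncol(raw))
  } else {
    norm <- (raw - rng[1]) / diff(rng)
  }
  if (flip_vertical) norm <- norm[rev(seq_len(nrow(norm))), , drop = FALSE]
  norm <- clamp01(resize_grid(norm, out_height, out_width))
  map$display <- list(norm = norm, rgb = colorize_density(norm))
  map
}

#' Grad-CAM explanations for a batch of samples
#'
#' Computes one post-processed map per (sample, class) pair and an overlay
#' blending the colormapped map onto the grayscale image channel.
#'
#' @param model a trained `gf_model`.
#' @param x input batch `H x W x C x N`.
#' @param classes class indices to explain (default: all classes).
#' @param target_layer hooked layer, see [capture_activations()].
#' @param alpha overlay blend weight of the map (default 0.4).
#' @param flip_vertical passed to [postprocess_cam()].
#' @return list of per-sample lists; element `[[n]][[c]]` has the
#'   `gradcam_map` (with display) and an `overlay` RGB array the size of the
#'   input image.
#' @export
explain_batch <- function(model, x, classes = NULL, target_layer = "conv2",
                          alpha = 0.4, flip_vertical = FALSE) {
  x <- as_batch(x)
  classes <- classes %||% seq_len(model$config$n_classes)
  h <- dim(x)[1]; w <- dim(x)[2]
  lapply(seq_len(dim(x)[4]), function(n) {
    xi <- x[, , , n, drop = FALSE]
    gray <- x[, , 1, n]
    out <- lapply(classes, function(cl) {
      cam <- postprocess_cam(gradcam(capture_activations(model, xi, cl,
                                                         target_layer)),
                             w, h, flip_vertical)
      overlay <- array(0, c(h, w, 3))
      for (chn in 1:3)
        overlay[, , chn] <- (1 - alpha) * gray + alpha * cam$display$rgb[, , chn]
      list(map = cam, overlay = overlay)
    })
    names(out) <- paste0("class_", classes)
    out
  })
}
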