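#' Stack a grayscale image and a fixation heatmap into a 4-channel input
#'
#' Early fusion along the channel dimension: channel 1 carries the grayscale
#' radiograph, channels 2-4 the RGB rendering of the fixation heatmap. Both
#' modalities must already be spatially registered (same width and height).
#'
#' @param image `H x W` grayscale matrix in \[0,1\].
#' @param heatmap a `fixation_heatmap` (its `rgb` field is used) or an
#'   `H x W x 3` RGB array.
#' @return `multimodal_input`: an `H x W x 4` array in \[0,1\].
#' @export
stack_multimodal <- function(image, heatmap) {
  rgb <- if (inherits(heatmap, "fixation_heatmap")) heatmap$rgb else heatmap
  if (!identical(dim(image), dim(rgb)[1:2]))
    stopf("image is %s but heatmap is %s",
          paste(dim(image), collapse = "x"),
          paste(dim(rgb)[1:2], collapse = "x"))
  out <- array(0, c(dim(image), 4))
  out[, , 1] <- image
  out[, , 2:4] <- rgb
  structure(out, class = c("multimodal_input", class(out)))
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

init_conv <- function(kh, kw, cin, cout) {
  list(W = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

init_fc <- function(d, k) {
  list(W = matrix(rnorm(d * k, 0, sqrt(2 / (d + k))), d, k),
       b = rep(0, k))
}

new_backbone_params <- function(cin, width) {
  list(conv1 = init_conv(3, 3, cin, width[1]),
       conv2 = init_conv(3, 3, width[1], width[2]))
}

#' Build the gaze-guided fusion model
#'
#' The architecture is: a spatial attention gate on the raw 4-channel stacked
#' input (two 1x1 convolutions — channel expansion with ReLU, then a score map
#' squashed to \[0,1\] by a sigmoid, optionally dropped out in training — whose
#' scores multiply the input elementwise), followed by a shared convolutional
#' backbone over all gated channels and an affine head producing one
#' independent logit per class for multilabel classification.
#'
#' The backbone is the package's compact seeded CNN: two 3x3 convolution
#' blocks (ReLU, 2x2 average pooling after the first) followed by global
#' max pooling, so the feature vector has dimension `width[2]` and the model
#' accepts any (even-sized) input resolution. Max pooling is the
#' multiple-instance readout appropriate for presence/absence of localized
#' findings: a small lesion drives its detector channel's peak regardless of
#' how little area it covers. The network trains from scratch on a CPU in
#' seconds to minutes at the phantom scale.
#'
#' @param input_channels number of input channels (4: grayscale + RGB
#'   heatmap).
#' @param n_classes number of output logits (default 6).
#' @param width channel widths of the two backbone convolution blocks.
#' @param gate_hidden intermediate channels of the gate's first 1x1
#'   convolution (default 8, the smallest nontrivial expansion of a 4-channel
#'   input).
#' @param gate_channels 1 (default) broadcasts a single score map over all
#'   input channels; `input_channels` gives per-channel scores.
#' @param dropout dropout rate applied to the attention scores in training
#'   (default 0.1).
#' @param seed integer seed for weight initialization.
#' @return a `gf_model` list (`type`, `config`, `params`).
#' @export
build_fusion_model <- function(input_channels = 4, n_classes = 6,
                               width = c(8, 16), gate_hidden = 8,
                               gate_channels = 1, dropout = 0.1,
                               seed = 42L) {
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (!gate_channels %in% c(1, input_channels))
    stopf("gate_channels must be 1 or input_channels")
  params <- with_seed(seed, {
    p <- list(gate = c(setNames(init_conv(1, 1, input_channels, gate_hidden),
                                c("W1", "b1")),
                       setNames(init_conv(1, 1, gate_hidden, gate_channels),
                                c("W2", "b2"))),
              backbone = new_backbone_params(input_channels, width))
    p$head <- init_fc(width[2], n_classes)
    p
  })
  structure(list(type = "fusion",
                 config = list(input_channels = input_channels,
                               n_classes = n_classes, width = width,
                               gate_hidden = gate_hidden,
                               gate_channels = gate_channels,
                               dropout = dropout, seed = seed),
                 params = params),
            class = "gf_model")
}

#' Build the image-only ablation baseline
#'
#' Same backbone and head contract as [build_fusion_model()] but with a
#' single grayscale input channel and no attention gate.
#'
#' @inheritParams build_fusion_model
#' @return a `gf_model`.
#' @export
build_image_only_model <- function(n_classes = 6, width = c(8, 16),
                                   seed = 42L) {
  params <- with_seed(seed, {
    p <- list(backbone = new_backbone_params(1, width))
    p$head <- init_fc(width[2], n_classes)
    p
  })
  structure(list(type = "image_only",
                 config = list(input_channels = 1, n_classes = n_classes,
                               width = width, dropout = 0, seed = seed),
                 params = params),
            class = "gf_model")
}

#' Build the no-shared-parameters late-fusion baseline
#'
#' Two parallel backbones — one over the grayscale channel, one over the RGB
#' heatmap channels — whose pooled features are concatenated before the
#' classification head. Serves as the comparison point for the shared-backbone
#' design in noise-robustness experiments.
#'
#' @inheritParams build_fusion_model
#' @return a `gf_model`.
#' @export
build_late_fusion_model <- function(n_classes = 6, width = c(8, 16),
                                    seed = 42L) {
  params <- with_seed(seed, {
    p <- list(backbone_img = new_backbone_params(1, width),
              backbone_hm = new_backbone_params(3, width))
    p$head <- init_fc(2 * width[2], n_classes)
    p
  })
  structure(list(type = "late_fusion",
                 config = list(input_channels = 4, n_classes = n_classes,
                               width = width, dropout = 0, seed = seed),
                 params = params),
            class = "gf_model")
}

#' @export
print.gf_model <- function(x, ...) {
  cat(sprintf("gf_model (%s): %d input channel(s), %d classes, %d parameters\n",
              x$type, x$config$input_channels, x$config$n_classes,
              n_params(x)))
  invisible(x)
}

#' Count trainable parameters of a model
#' @param model a `gf_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity,
             numeric(1)))
}

as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1, 1)
  x
}

#' Apply the attention gate to a feature grid
#'
#' Computes `F_conv1 = ReLU(W1 * F_input + b1)`, scores
#' `A = sigmoid(W2 * F_conv1 + b2)` (with optional dropout on the scores in
#' training mode), and returns the attended features `F_input * A`. Scores lie
#' in \[0,1\] elementwise; a single-channel score map broadcasts over all input
#' channels.
#'
#' @param x input array `H x W x C` or `H x W x C x N`.
#' @param params list with `W1`, `b1`, `W2`, `b2` (1x1 convolution weights)
#'   and optionally `dropout_rate`.
#' @param train_mode apply dropout to the scores (uses the current RNG state).
#' @return list with `attended` (same shape as `x`) and `scores`.
#' @export
attention_gate <- function(x, params, train_mode = FALSE) {
  x <- as_batch(x)
  if (dim(x)[3] != dim(params$W1)[3])
    stopf("input has %d channels but gate expects %d",
          dim(x)[3], dim(params$W1)[3])
  a1 <- relu(conv2d_fwd_cpp(x, params$W1, params$b1, 0L))
  s <- sigmoid(conv2d_fwd_cpp(a1, params$W2, params$b2, 0L))
  p <- params$dropout_rate %||% 0
  if (train_mode && p > 0) {
    mask <- array(rbinom(length(s), 1, 1 - p) / (1 - p), dim(s))
    s_used <- s * mask
  } else s_used <- s
  gc <- dim(s)[3]
  s_full <- if (gc == 1) s_used[, , rep(1, dim(x)[3]), , drop = FALSE] else s_used
  list(attended = x * s_full, scores = s)
}

backbone_forward <- function(bp, x) {
  z1 <- conv2d_fwd_cpp(x, bp$conv1$W, bp$conv1$b, 1L)
  a1 <- relu(z1)
  p1 <- avgpool2_fwd_cpp(a1)
  z2 <- conv2d_fwd_cpp(p1, bp$conv2$W, bp$conv2$b, 1L)
  a2 <- relu(z2)
  d <- dim(a2)
  # global max pooling: multiple-instance readout of "pattern present
  # anywhere"; ties broken by first index for determinism
  m2 <- matrix(a2, d[1] * d[2], d[3] * d[4])
  amax <- max.col(t(m2), ties.method = "first")
  f <- matrix(m2[cbind(amax, seq_along(amax))], d[3], d[4])
  list(x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2, a2 = a2, f = f,
       amax = amax)
}

backbone_backward <- function(bp, cache, df) {
  d <- dim(cache$a2)
  da2 <- array(0, d)
  flat <- cache$amax + (seq_along(cache$amax) - 1) * d[1] * d[2]
  da2[flat] <- as.vector(df)
  dz2 <- da2 * (cache$z2 > 0)
  g2 <- conv2d_bwd_cpp(cache$p1, bp$conv2$W, dz2, 1L)
  da1 <- avgpool2_bwd_cpp(g2$dx)
  dz1 <- da1 * (cache$z1 > 0)
  g1 <- conv2d_bwd_cpp(cache$x, bp$conv1$W, dz1, 1L)
  list(grads = list(conv1 = list(W = g1$dw, b = g1$db),
                    conv2 = list(W = g2$dw, b = g2$db)),
       dx = g1$dx)
}

#' Forward pass of a model
#'
#' Evaluation mode is a pure, deterministic function of the input and the
#' weights; training mode additionally applies seeded dropout on the attention
#' scores (fusion model only). Set `cache = TRUE` to retain the intermediate
#' activations needed by the training engine and by Grad-CAM.
#'
#' @param model a `gf_model`.
#' @param x input array `H x W x C` (single sample) or `H x W x C x N`.
#' @param train_mode training-mode stochastic layers active.
#' @param cache keep intermediates.
#' @return list with `logits` (`N x n_classes` matrix) and, if requested,
#'   `cache`.
#' @export
model_forward <- function(model, x, train_mode = FALSE, cache = FALSE) {
  x <- as_batch(x)
  cfg <- model$config
  if (dim(x)[3] != cfg$input_channels)
    stopf("input has %d channels but model expects %d",
          dim(x)[3], cfg$input_channels)
  p <- model$params
  ch <- list()
  if (model$type == "fusion") {
    gp <- p$gate
    gp$dropout_rate <- cfg$dropout
    a1g <- relu(conv2d_fwd_cpp(x, gp$W1, gp$b1, 0L))
    s <- sigmoid(conv2d_fwd_cpp(a1g, gp$W2, gp$b2, 0L))
    if (train_mode && cfg$dropout > 0) {
      mask <- array(rbinom(length(s), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
                    dim(s))
    } else mask <- array(1, dim(s))
    s_used <- s * mask
    s_full <- if (cfg$gate_channels == 1)
      s_used[, , rep(1, dim(x)[3]), , drop = FALSE] else s_used
    xa <- x * s_full
    bb <- backbone_forward(p$backbone, xa)
    feat <- bb$f
    ch <- list(x = x, a1g = a1g, s = s, mask = mask, bb = bb)
  } else if (model$type == "image_only") {
    bb <- backbone_forward(p$backbone, x)
    feat <- bb$f
    ch <- list(bb = bb)
  } else { # late_fusion
    bi <- backbone_forward(p$backbone_img, x[, , 1, , drop = FALSE])
    bh <- backbone_forward(p$backbone_hm, x[, , 2:4, , drop = FALSE])
    feat <- rbind(bi$f, bh$f)
    ch <- list(bi = bi, bh = bh)
  }
  logits <- t(feat) %*% p$head$W + matrix(p$head$b, ncol(feat),
                                          cfg$n_classes, byrow = TRUE)
  if (any(!is.finite(logits))) stopf("non-finite logits in forward pass")
  out <- list(logits = logits)
  if (cache) out$cache <- c(ch, list(feat = feat))
  out
}

# Gradients of the mean multilabel BCE loss w.r.t. all parameters.
# dlogits: N x K matrix of dLoss/dlogits.
model_backward <- function(model, x, fwd, dlogits) {
  p <- model$params
  ch <- fwd$cache
  feat <- ch$feat
  grads <- list(head = list(W = feat %*% dlogits,
                            b = colSums(dlogits)))
  df <- p$head$W %*% t(dlogits) # D x N
  if (model$type == "image_only") {
    bb <- backbone_backward(p$backbone, ch$bb, df)
    grads$backbone <- bb$grads
  } else if (model$type == "late_fusion") {
    d2 <- model$config$width[2]
    bi <- backbone_backward(p$backbone_img, ch$bi, df[seq_len(d2), , drop = FALSE])
    bh <- backbone_backward(p$backbone_hm, ch$bh,
                            df[d2 + seq_len(d2), , drop = FALSE])
    grads$backbone_img <- bi$grads
    grads$backbone_hm <- bh$grads
  } else { # fusion
    bb <- backbone_backward(p$backbone, ch$bb, df)
    grads$backbone <- bb$grads
    dxa <- bb$dx
    xin <- ch$x
    s_used <- ch$s * ch$mask
    gc <- model$config$gate_channels
    if (gc == 1) {
      dsx <- dxa * xin
      ds_used <- array(0, dim(ch$s))
      for (c in seq_len(dim(xin)[3]))
        ds_used <- ds_used + dsx[, , c, , drop = FALSE]
    } else ds_used <- dxa * xin
    ds <- ds_used * ch$mask
    dz2g <- ds * ch$s * (1 - ch$s)
    g2 <- conv2d_bwd_cpp(ch$a1g, p$gate$W2, dz2g, 0L)
    dz1g <- g2$dx * (ch$a1g > 0)
    g1 <- conv2d_bwd_cpp(xin, p$gate$W1, dz1g, 0L)
    grads$gate <- list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db)
  }
  grads
}

#' Convert logits to sigmoid probabilities and thresholded labels
#'
#' `p_k = 1 / (1 + exp(-x_k))`; the binary label is 1 where
#' `p_k >= threshold`.
#'
#' @param logits numeric vector or `N x K` matrix of finite logits.
#' @param threshold decision cutoff (default 0.5).
#' @return list with `probs` and `labels`, shaped like `logits`.
#' @export
predict_probs <- function(logits, threshold = 0.5) {
  probs <- sigmoid(logits)
  list(probs = probs, labels = (probs >= threshold) * 1L)
}

#' Predict class probabilities for a batch
#'
#' @param model a `gf_model`.
#' @param x input batch `H x W x C x N`.
#' @param batch_size forward-pass chunk size.
#' @return `N x n_classes` probability matrix.
#' @export
model_predict <- function(model, x, batch_size = 64) {
  x <- as_batch(x)
  n <- dim(x)[4]
  out <- matrix(0, n, model$config$n_classes)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    out[idx, ] <- sigmoid(model_forward(model,
                                        x[, , , idx, drop = FALSE])$logits)
  }
  out
}

#' Save / load a model
#'
#' The serialized file embeds the full config (type, backbone widths, gate
#' settings, seed) alongside the weights.
#'
#' @param model a `gf_model`.
#' @param path file path.
#' @return `load_model` returns the `gf_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gf_model")) stopf("%s is not a serialized gf_model", path)
  m
}
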