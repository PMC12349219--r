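#' Training configuration
#'
#' Defaults follow the protocol used for the full-scale radiograph
#' experiments: Adam with learning rate 5e-5 and weight decay 1e-3, batch
#' size 32, 20 epochs, an 80/10/10 train/validation/test split, and seed 42.
#' For the compact backbone trained from scratch on phantoms, a larger
#' learning rate (1e-3) is the appropriate choice — see the methods vignette.
#'
#' @param epochs number of training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the gradients.
#' @param batch_size minibatch size.
#' @param optimizer only `"adam"` is provided.
#' @param split train/validation/test fractions, summing to 1.
#' @param seed integer seed governing the shuffle, dropout and any other
#'   training-time randomness.
#' @param early_stop_patience halt when validation loss has risen strictly
#'   for this many consecutive epochs; `NULL` (default) disables early
#'   stopping.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20, learning_rate = 5e-5,
                         weight_decay = 1e-3, batch_size = 32,
                         optimizer = "adam", split = c(0.8, 0.1, 0.1),
                         seed = 42L, early_stop_patience = NULL) {
  if (abs(sum(split) - 1) > 1e-9) stopf("split fractions must sum to 1")
  if (epochs < 0 || learning_rate <= 0 || weight_decay < 0 || batch_size < 1)
    stopf("epochs/learning_rate/weight_decay/batch_size out of range")
  if (!identical(optimizer, "adam")) stopf("unsupported optimizer: %s", optimizer)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 split = split, seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

#' Split samples into train/validation/test partitions
#'
#' Seeded shuffle followed by a disjoint, exhaustive partition at the given
#' fractions.
#'
#' @param samples a list (or vector) of samples.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed shuffle seed.
#' @return list with `train`, `val`, `test` subsets (same type as `samples`)
#'   and an `indices` attribute holding the three index vectors.
#' @export
split_dataset <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 42L) {
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  n <- length(samples)
  if (n < 3) stopf("need at least 3 samples to split, got %d", n)
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  parts <- list(train = sort(idx[seq_len(n_train)]),
                val = sort(idx[n_train + seq_len(n_val)]),
                test = sort(idx[-seq_len(n_train + n_val)]))
  structure(list(train = samples[parts$train], val = samples[parts$val],
                 test = samples[parts$test]),
            indices = parts)
}

#' Multilabel binary cross-entropy from logits
#'
#' Mean over samples and classes of the per-label sigmoid cross-entropy,
#' computed in the numerically stable logits form.
#'
#' @param logits `N x K` logit matrix.
#' @param labels `N x K` 0/1 matrix.
#' @return scalar loss.
#' @export
bce_loss <- function(logits, labels) {
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# Recursive helpers over nested parameter lists (leaves are numeric arrays).
params_map <- function(p, f) {
  if (is.list(p)) lapply(p, params_map, f = f) else f(p)
}
params_map2 <- function(a, b, f) {
  if (is.list(a)) Map(params_map2, a, b, MoreArgs = list(f = f)) else f(a, b)
}

adam_step <- function(params, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- lapply(names(p), function(nm) walk(p[[nm]], g[[nm]],
                                                m[[nm]], v[[nm]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, state$m, state$v)
}

# Validation-loss early stop: triggered when the last `patience` epoch-to-
# epoch changes are all strictly positive.
early_stop_triggered <- function(val_losses, patience) {
  if (is.null(patience) || length(val_losses) <= patience) return(FALSE)
  d <- diff(utils::tail(val_losses, patience + 1))
  all(d > 0)
}

#' Train a model with Adam on multilabel BCE
#'
#' Runs exactly `config$epochs` epochs (fewer if early stopping is enabled
#' and triggers), fully seeded: the same model, data, and config reproduce
#' identical loss curves and weights. Loss is the unweighted mean binary
#' cross-entropy across the class sigmoids.
#'
#' @param model a `gf_model`.
#' @param x training inputs `H x W x C x N`.
#' @param y training labels `N x K` 0/1 matrix.
#' @param val_x,val_y optional validation set (required for early stopping).
#' @param config a [train_config()].
#' @return list with `model` (trained), `curves` (data frame: epoch,
#'   train_loss, val_loss).
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL, config) {
  x <- as_batch(x)
  y <- as.matrix(y)
  n <- dim(x)[4]
  if (n == 0) stopf("training set is empty")
  if (nrow(y) != n) stopf("labels (%d rows) do not match inputs (%d)", nrow(y), n)
  if (ncol(y) != model$config$n_classes)
    stopf("labels have %d classes but the model head has %d",
          ncol(y), model$config$n_classes)
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  if (config$epochs == 0) return(list(model = model, curves = curves))
  state <- list(m = params_map(model$params, function(p) p * 0),
                v = params_map(model$params, function(p) p * 0))
  t_step <- 0
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      losses <- numeric(0); sizes <- numeric(0)
      for (i0 in seq(1, n, by = config$batch_size)) {
        bi <- idx[i0:min(i0 + config$batch_size - 1, n)]
        xb <- x[, , , bi, drop = FALSE]
        yb <- y[bi, , drop = FALSE]
        fwd <- model_forward(model, xb, train_mode = TRUE, cache = TRUE)
        loss <- bce_loss(fwd$logits, yb)
        if (!is.finite(loss))
          stopf("non-finite training loss at epoch %d (batch starting %d); %s",
                epoch, i0, "try a smaller learning rate")
        dlogits <- (sigmoid(fwd$logits) - yb) / length(yb)
        grads <- model_backward(model, xb, fwd, dlogits)
        t_step <- t_step + 1
        upd <- adam_step(model$params, grads, state, config$learning_rate,
                         config$weight_decay, t_step)
        model$params <- upd$p
        state$m <- upd$m
        state$v <- upd$v
        losses <- c(losses, loss); sizes <- c(sizes, length(bi))
      }
      train_loss <- sum(losses * sizes) / sum(sizes)
      val_loss <- if (!is.null(val_x)) {
        vl <- model_forward(model, as_batch(val_x))$logits
        bce_loss(vl, as.matrix(val_y))
      } else NA_real_
      curves <- rbind(curves, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
      if (!is.na(val_loss) &&
          early_stop_triggered(curves$val_loss, config$early_stop_patience))
        break
    }
  })
  list(model = model, curves = curves)
}

#' Assemble network inputs from a phantom dataset
#'
#' Renders each sample's fixation heatmap from its own gaze table and stacks
#' it with the image (fusion mode), or extracts the grayscale channel alone
#' (image-only mode).
#'
#' @param dataset a `phantom_dataset`.
#' @param mode `"fusion"` (4 channels) or `"image_only"` (1 channel).
#' @param sigma heatmap kernel bandwidth; default `image_size / 25`.
#' @return list with `x` (`H x W x C x N` array) and `y` (`N x K` label
#'   matrix).
#' @export
build_inputs <- function(dataset, mode = c("fusion", "image_only"),
                         sigma = NULL) {
  mode <- match.arg(mode)
  cfg <- attr(dataset, "config")
  size <- cfg$image_size
  sigma <- sigma %||% (size / 25)
  n <- length(dataset)
  nc <- if (mode == "fusion") 4 else 1
  x <- array(0, c(size, size, nc, n))
  y <- matrix(0L, n, cfg$n_classes)
  for (i in seq_len(n)) {
    s <- dataset[[i]]
    if (mode == "fusion") {
      hm <- render_fixation_heatmap(s$gaze, size, size, sigma = sigma)
      x[, , , i] <- stack_multimodal(s$image, hm)
    } else {
      x[, , 1, i] <- s$image
    }
    y[i, ] <- s$labels
  }
  list(x = x, y = y)
}
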