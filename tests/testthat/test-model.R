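test_that("multimodal stacking preserves channels and checks shapes", {
  img <- matrix(runif(224 * 224), 224, 224)
  zero_hm <- structure(list(density = matrix(0, 224, 224),
                            rgb = array(0, c(224, 224, 3))),
                       class = "fixation_heatmap")
  x <- stack_multimodal(img, zero_hm)
  expect_equal(dim(x), c(224, 224, 4))
  expect_identical(x[, , 1], img)
  expect_true(all(x[, , 2:4] == 0))
  small <- array(0, c(112, 112, 3))
  expect_error(stack_multimodal(img, small), "224x224.*112x112")
})

test_that("attention gate reduces to sigmoid algebra in degenerate settings", {
  x <- random_batch(8, 8, 4, 2)
  params <- list(W1 = array(rnorm(4 * 8, 0, 0.5), c(1, 1, 4, 8)),
                 b1 = rnorm(8),
                 W2 = array(0, c(1, 1, 8, 1)), b2 = 0)
  out <- attention_gate(x, params)
  expect_equal(out$attended, x * 0.5, tolerance = 1e-12)
  expect_true(all(out$scores == 0.5))
  params$b2 <- 20
  out2 <- attention_gate(x, params)
  expect_lt(max(abs(out2$attended - x)), 1e-8)
})

test_that("attention gate matches a per-pixel composition oracle", {
  withr::with_seed(31L, {
    x <- array(runif(4 * 8 * 8), c(8, 8, 4, 1))
    params <- list(W1 = array(rnorm(4 * 8, 0, 0.4), c(1, 1, 4, 8)),
                   b1 = rnorm(8, 0, 0.2),
                   W2 = array(rnorm(8, 0, 0.4), c(1, 1, 8, 1)),
                   b2 = rnorm(1, 0, 0.2))
  })
  out <- attention_gate(x, params)
  scores <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    h <- pmax(colSums(x[i, j, , 1] * params$W1[1, 1, , ]) + params$b1, 0)
    scores[i, j] <- 1 / (1 + exp(-(sum(h * params$W2[1, 1, , 1]) + params$b2)))
  }
  for (c in 1:4)
    expect_lt(max(abs(out$attended[, , c, 1] - x[, , c, 1] * scores)), 1e-6)
  expect_true(all(out$scores >= 0 & out$scores <= 1))
  expect_true(all(abs(out$attended) <= abs(x) + 1e-12))
  bad <- list(W1 = array(0, c(1, 1, 3, 8)), b1 = rep(0, 8),
              W2 = array(0, c(1, 1, 8, 1)), b2 = 0)
  expect_error(attention_gate(x, bad), "channels")
})

test_that("gate scores stay in [0,1] for extreme inputs", {
  params <- list(W1 = array(rnorm(4 * 8, 0, 3), c(1, 1, 4, 8)),
                 b1 = rnorm(8, 0, 3),
                 W2 = array(rnorm(8, 0, 3), c(1, 1, 8, 1)), b2 = 5)
  for (scale in c(0, 1, 100)) {
    out <- attention_gate(random_batch(6, 6, 4, 1, seed = 44L) * scale, params)
    expect_true(all(out$scores >= 0 & out$scores <= 1))
  }
})

test_that("evaluation-mode forward is deterministic and respects contracts", {
  m <- build_fusion_model(seed = 3L)
  x <- random_batch(32, 32, 4, 2)
  l1 <- model_forward(m, x)$logits
  l2 <- model_forward(m, x)$logits
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(2, 6))
  expect_true(all(is.finite(l1)))
  expect_error(model_forward(m, random_batch(32, 32, 3, 1)), "channels")
})

test_that("image-only baseline is smaller and seeded builds are identical", {
  mf <- build_fusion_model(seed = 5L)
  mi <- build_image_only_model(seed = 5L)
  expect_lt(n_params(mi), n_params(mf))
  expect_identical(build_fusion_model(seed = 5L)$params, mf$params)
  expect_false(identical(build_fusion_model(seed = 6L)$params, mf$params))
  # shared components initialize identically under the same seed: the conv2
  # stage (whose fan-in does not depend on the input channels) matches
  expect_identical(dim(mf$params$backbone$conv2$W),
                   dim(mi$params$backbone$conv2$W))
  li <- model_forward(mi, random_batch(16, 16, 1, 2))$logits
  expect_equal(dim(li), c(2, 6))
})

test_that("late-fusion baseline leaves modalities in separate backbones", {
  m <- build_late_fusion_model(seed = 2L)
  x <- random_batch(16, 16, 4, 2)
  l <- model_forward(m, x)$logits
  expect_equal(dim(l), c(2, 6))
  # image branch output is unaffected by heatmap channels
  x2 <- x
  x2[, , 2:4, ] <- 0
  f1 <- model_forward(m, x, cache = TRUE)$cache$bi$f
  f2 <- model_forward(m, x2, cache = TRUE)$cache$bi$f
  expect_identical(f1, f2)
})

test_that("every parameter tensor receives gradient on a generic batch", {
  m <- build_fusion_model(seed = 9L)
  x <- random_batch(16, 16, 4, 4, seed = 10L)
  y <- random_labels(4)
  fwd <- model_forward(m, x, cache = TRUE)
  dlog <- (1 / (1 + exp(-fwd$logits)) - y) / length(y)
  grads <- gazefusion:::model_backward(m, x, fwd, dlog)
  leaves <- rapply(grads, function(g) any(g != 0), how = "unlist")
  expect_true(all(leaves))
})

test_that("probability head follows the sigmoid identities", {
  p <- predict_probs(c(0, 10, -10))
  expect_equal(p$probs[1], 0.5)
  expect_equal(p$labels, c(1L, 1L, 0L))
  withr::with_seed(12L, z <- runif(1000, -30, 30))
  s <- predict_probs(z)$probs + predict_probs(-z)$probs
  expect_lt(max(abs(s - 1)), 1e-12)
})

test_that("models round-trip through serialization", {
  m <- build_fusion_model(seed = 17L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  x <- random_batch(16, 16, 4, 1)
  expect_identical(model_forward(m, x)$logits, model_forward(m2, x)$logits)
})
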