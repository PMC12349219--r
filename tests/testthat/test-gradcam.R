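test_that("capture shapes follow the hooked layer and weights are untouched", {
  m <- build_fusion_model(seed = 50L)
  x <- random_batch(16, 16, 4, 1, seed = 51L)
  before <- m$params
  cap2 <- capture_activations(m, x, target_class = 2, "conv2")
  cap1 <- capture_activations(m, x, target_class = 2, "conv1")
  expect_equal(dim(cap2$activations), c(8, 8, 16))
  expect_equal(dim(cap2$gradients), dim(cap2$activations))
  expect_equal(cap2$Z, 64)
  expect_equal(dim(cap1$activations), c(16, 16, 8))
  expect_identical(m$params, before)
  expect_error(capture_activations(m, x, 9), "target_class")
  expect_error(capture_activations(m, x, 1, "conv7"), "target_layer")
})

test_that("different target classes give different gradients", {
  m <- build_fusion_model(seed = 52L)
  x <- random_batch(16, 16, 4, 1, seed = 53L)
  g1 <- capture_activations(m, x, 1)$gradients
  g2 <- capture_activations(m, x, 2)$gradients
  expect_false(identical(g1, g2))
  a1 <- capture_activations(m, x, 1)$activations
  a2 <- capture_activations(m, x, 2)$activations
  expect_identical(a1, a2) # activations do not depend on the class
})

test_that("uniform positive gradients reduce to the closed form", {
  withr::with_seed(54L, A <- array(runif(36), c(6, 6, 1)))
  g <- 0.37
  cap <- structure(list(activations = A,
                        gradients = array(g, c(6, 6, 1)),
                        Z = 36, layer = "conv2", target_class = 1),
                   class = "activation_capture")
  map <- gradcam(cap)
  expect_equal(map$weights, g)
  expect_equal(map$raw, pmax(g * A[, , 1], 0), tolerance = 1e-12)
})

test_that("all-negative gradients with nonnegative activations kill the map", {
  withr::with_seed(55L, A <- array(runif(72), c(6, 6, 2)))
  cap <- structure(list(activations = A,
                        gradients = array(-abs(rnorm(72)), c(6, 6, 2)),
                        Z = 36, layer = "conv2", target_class = 1),
                   class = "activation_capture")
  expect_true(all(gradcam(cap)$raw == 0))
})

test_that("module output equals the brute-force loop oracle", {
  m <- build_fusion_model(seed = 56L)
  x <- random_batch(8, 8, 4, 1, seed = 57L)
  for (layer in c("conv2", "conv1")) {
    cap <- capture_activations(m, x, target_class = 3, layer)
    map <- gradcam(cap)
    K <- dim(cap$activations)[3]
    alpha <- numeric(K)
    for (k in seq_len(K)) {
      s <- 0
      for (i in seq_len(dim(cap$gradients)[1]))
        for (j in seq_len(dim(cap$gradients)[2]))
          s <- s + cap$gradients[i, j, k]
      alpha[k] <- s / cap$Z
    }
    raw <- matrix(0, dim(cap$activations)[1], dim(cap$activations)[2])
    for (k in seq_len(K)) raw <- raw + alpha[k] * cap$activations[, , k]
    raw[raw < 0] <- 0
    expect_lt(max(abs(map$raw - raw)), 1e-5)
    expect_equal(map$weights, alpha, tolerance = 1e-10)
  }
})

test_that("captured gradients agree with the max-pool head analytic form", {
  # y_c = sum_k W[k,c] * max_ij A2[i,j,k] + b_c, so dy/dA2 is W[k,c] at each
  # feature map's peak and zero elsewhere
  m <- build_image_only_model(seed = 58L)
  x <- random_batch(16, 16, 1, 1, seed = 59L)
  cap <- capture_activations(m, x, 4, "conv2")
  W <- m$params$head$W[, 4]
  for (k in seq_len(dim(cap$activations)[3])) {
    gk <- cap$gradients[, , k]
    am <- which(cap$activations[, , k] == max(cap$activations[, , k]),
                arr.ind = TRUE)[1, ]
    expect_equal(gk[am[1], am[2]], W[k])
    expect_equal(sum(gk != 0), 1)
  }
})

test_that("scaling the head row scales the raw map but not the display", {
  m <- build_fusion_model(seed = 60L)
  x <- random_batch(16, 16, 4, 1, seed = 61L)
  map1 <- gradcam(capture_activations(m, x, 1))
  m2 <- m
  m2$params$head$W[, 1] <- 3 * m2$params$head$W[, 1]
  map2 <- gradcam(capture_activations(m2, x, 1))
  expect_equal(map2$raw, 3 * map1$raw, tolerance = 1e-10)
  if (max(map1$raw) > 0) {
    d1 <- postprocess_cam(map1, 16, 16)$display$norm
    d2 <- postprocess_cam(map2, 16, 16)$display$norm
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("post-processing normalizes, flips and upscales as specified", {
  const <- structure(list(raw = matrix(2, 7, 7), weights = 1,
                          layer = "conv2", target_class = 1),
                     class = "gradcam_map")
  expect_warning(out <- postprocess_cam(const, 14, 14), "constant")
  expect_true(all(out$display$norm == 0))
  withr::with_seed(62L, {
    map <- structure(list(raw = matrix(runif(49), 7, 7), weights = 1,
                          layer = "conv2", target_class = 1),
                     class = "gradcam_map")
  })
  once <- postprocess_cam(map, 7, 7, flip_vertical = TRUE)$display$norm
  twice <- postprocess_cam(
    structure(list(raw = once, weights = 1, layer = "conv2",
                   target_class = 1), class = "gradcam_map"),
    7, 7, flip_vertical = TRUE)$display$norm
  rng <- range(map$raw)
  expect_equal(twice, (map$raw - rng[1]) / diff(rng), tolerance = 1e-9)
  up <- postprocess_cam(map, 224, 224)
  expect_equal(dim(up$display$norm), c(224, 224))
  am_raw <- which(map$raw == max(map$raw), arr.ind = TRUE)[1, ]
  am_up <- which(up$display$norm == max(up$display$norm), arr.ind = TRUE)[1, ]
  expect_lte(abs(am_up[1] - (am_raw[1] - 0.5) * 32), 32)
  expect_lte(abs(am_up[2] - (am_raw[2] - 0.5) * 32), 32)
  expect_error(postprocess_cam(map, 0, 10), "positive")
})

test_that("explain_batch produces one overlay per class at image size", {
  m <- build_fusion_model(n_classes = 2, seed = 63L)
  x <- random_batch(16, 16, 4, 2, seed = 64L)
  ex <- explain_batch(m, x)
  expect_length(ex, 2)
  expect_named(ex[[1]], c("class_1", "class_2"))
  expect_equal(dim(ex[[1]]$class_1$overlay), c(16, 16, 3))
  expect_true(all(ex[[1]]$class_2$map$raw >= 0))
  # zeroing a class's head row erases its map
  m$params$head$W[, 1] <- 0
  ex0 <- explain_batch(m, x, classes = 1)
  expect_true(all(ex0[[1]]$class_1$map$raw == 0))
})
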