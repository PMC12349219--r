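# Brute-force pair-counting AUC (ties count half).
auc_oracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

test_that("perfect predictions score 1 everywhere with clean confusions", {
  y <- random_labels(30, 3, seed = 70L)
  y[1, ] <- c(1, 0, 1) # guarantee both label values per class
  y[2, ] <- c(0, 1, 0)
  met <- classification_metrics(ifelse(y == 1, 0.9, 0.1), y)
  expect_true(all(met$per_class[, c("accuracy", "precision", "recall",
                                    "f1", "auc")] == 1))
  expect_true(all(met$per_class$fp == 0) && all(met$per_class$fn == 0))
})

test_that("hand-computed confusion example gives the textbook metrics", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.1, 0.1)
  # TP=2 FP=1 FN=1 TN=4
  met <- classification_metrics(matrix(p), matrix(y))
  row <- met$per_class[1, ]
  expect_equal(row$tp, 2); expect_equal(row$fp, 1)
  expect_equal(row$fn, 1); expect_equal(row$tn, 4)
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 2 / 3)
  expect_equal(row$f1, 2 / 3)
  expect_equal(row$accuracy, 3 / 4)
})

test_that("label-independent probabilities give chance-level macro AUC", {
  withr::with_seed(71L, {
    y <- matrix(rbinom(10000, 1, 0.5), 10000, 1)
    p <- matrix(runif(10000), 10000, 1)
  })
  expect_lt(abs(macro_auc(p, y) - 0.5), 0.02)
})

test_that("AUC matches the pair-counting oracle and is rank-invariant", {
  withr::with_seed(72L, {
    y <- rbinom(60, 1, 0.4)
    y[1:2] <- c(0, 1)
    p <- round(runif(60), 2) # ties included
  })
  ref <- auc_oracle(p, y)
  expect_equal(macro_auc(matrix(p), matrix(y)), ref, tolerance = 1e-12)
  expect_equal(macro_auc(matrix(plogis(5 * p - 2)), matrix(y)), ref,
               tolerance = 1e-12)
})

test_that("degenerate classes are reported NA and excluded with a warning", {
  y <- cbind(c(1, 0, 1, 0), c(0, 0, 0, 0))
  p <- cbind(c(0.9, 0.2, 0.8, 0.1), c(0.4, 0.2, 0.1, 0.3))
  expect_warning(met <- classification_metrics(p, y), "excluded")
  expect_true(is.na(met$per_class$recall[2]))
  expect_true(is.na(met$per_class$auc[2]))
  expect_equal(met$macro[["recall"]], 1)
  expect_error(classification_metrics(p, y[, 1, drop = FALSE]), "shapes")
  expect_error(classification_metrics(p, y, threshold = 1.2), "threshold")
})

test_that("reported confusion counts reproduce the reported accuracy", {
  withr::with_seed(73L, {
    y <- matrix(rbinom(200 * 4, 1, 0.3), 200, 4)
    p <- matrix(runif(800), 200, 4)
  })
  met <- suppressWarnings(classification_metrics(p, y))
  with(met$per_class, {
    expect_equal((tp + tn) / (tp + fp + fn + tn), accuracy)
    expect_true(all(tp + fp + fn + tn == 200))
  })
})

test_that("CAM binarization thresholds and nests correctly", {
  expect_true(all(binarize_cam(matrix(0, 4, 4), 0.5) == FALSE))
  withr::with_seed(74L, d <- matrix(runif(64), 8, 8))
  masks <- lapply(c(0.8, 0.5, 0.2), binarize_cam, display = d)
  expect_true(all(masks[[2]][masks[[1]]]))  # 0.8-mask nested in 0.5-mask
  expect_true(all(masks[[3]][masks[[2]]]))
  d2 <- d; d2[3, 4] <- 2 # unique maximum
  expect_equal(which(binarize_cam(d2 / 2, 0.99)), which(d2 == 2))
  expect_error(binarize_cam(d, 0), "threshold")
})

test_that("IoU follows set algebra on hand-countable masks", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(compute_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(compute_iou(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[1:2, 2:3] <- TRUE
  expect_equal(compute_iou(a, c2), 1 / 3) # intersection 2, union 6
  expect_equal(compute_iou(a, c2), compute_iou(c2, a))
  expect_equal(compute_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(compute_iou(a, matrix(FALSE, 2, 2)), "shapes")
})

test_that("mIoU is the unweighted mean with empty-ROI classes excluded", {
  half <- matrix(FALSE, 4, 4); half[1:2, ] <- TRUE
  quarter <- matrix(FALSE, 4, 4); quarter[1:2, 1:2] <- TRUE # IoU vs half: 0.5
  rep1 <- compute_miou(list(a = quarter, b = half),
                       list(a = half, b = half))
  expect_equal(unname(rep1$per_class_iou), c(0.5, 1))
  expect_equal(rep1$miou, 0.75)
  expect_equal(rep1$n_classes, 2)
  empty <- matrix(FALSE, 4, 4)
  expect_warning(
    rep2 <- compute_miou(list(a = quarter, b = empty),
                         list(a = half, b = empty)),
    "excluded")
  expect_equal(rep2$miou, 0.5)
  expect_equal(rep2$n_classes, 1)
  expect_error(compute_miou(list(), list()), "empty")
  expect_error(compute_miou(list(a = half), list(b = half)), "class set")
})

test_that("mIoU agrees with a brute-force per-pixel loop", {
  withr::with_seed(75L, {
    cams <- lapply(1:3, function(i) matrix(runif(36) > 0.5, 6, 6))
    rois <- lapply(1:3, function(i) matrix(runif(36) > 0.4, 6, 6))
  })
  names(cams) <- names(rois) <- paste0("c", 1:3)
  rep <- compute_miou(cams, rois)
  loop <- vapply(1:3, function(k) {
    inter <- 0; uni <- 0
    for (i in 1:6) for (j in 1:6) {
      inter <- inter + (cams[[k]][i, j] && rois[[k]][i, j])
      uni <- uni + (cams[[k]][i, j] || rois[[k]][i, j])
    }
    inter / uni
  }, numeric(1))
  expect_equal(unname(rep$per_class_iou), loop, tolerance = 1e-12)
  expect_equal(rep$miou, mean(loop), tolerance = 1e-12)
})
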