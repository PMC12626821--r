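# Hybrid loss, the seven segmentation metrics, ROC/AUC, run aggregation and
# the paired t-test.

random_probmask <- function(H, W, K, seed) {
  withr::with_seed(seed, {
    z <- array(stats::rnorm(H * W * K), c(H, W, K))
    p <- exp(z)
    tot <- apply(p, c(1, 2), sum)
    for (k in seq_len(K)) p[, , k] <- p[, , k] / tot
    list(p = p, y = matrix(sample(0:(K - 1), H * W, TRUE), H, W))
  })
}

test_that("cross-entropy matches closed forms", {
  # uniform 6-class prediction: ln 6 per pixel
  p <- array(1 / 6, c(4, 4, 6))
  y <- matrix(sample(0:5, 16, TRUE), 4, 4)
  expect_equal(cross_entropy_loss(p, y), log(6), tolerance = 1e-9)
  # perfect one-hot: loss at the clipping floor
  p1 <- array(0, c(2, 2, 3)); y1 <- matrix(c(0, 1, 2, 0), 2, 2)
  for (i in 1:2) for (j in 1:2) p1[i, j, y1[i, j] + 1] <- 1
  expect_lt(cross_entropy_loss(p1, y1), 1e-6)
  # two pixels with true-class probabilities 0.5 and 0.25
  p2 <- array(0, c(1, 2, 2))
  p2[1, 1, ] <- c(0.5, 0.5); p2[1, 2, ] <- c(0.25, 0.75)
  y2 <- matrix(c(0L, 0L), 1, 2)
  expect_equal(cross_entropy_loss(p2, y2), (log(2) + log(4)) / 2,
               tolerance = 1e-9)
  # labels outside the class range are rejected
  expect_error(cross_entropy_loss(p, matrix(7L, 4, 4)),
               class = "melseg_error_validation")
})

test_that("focal loss reduces to cross-entropy at gamma = 0, alpha = 1", {
  cfg0 <- loss_config(gamma = 0, alpha = 1)
  for (s in 1:100) {
    pm <- random_probmask(6, 6, 6, seed = s)
    expect_equal(focal_loss(pm$p, pm$y, cfg0),
                 cross_entropy_loss(pm$p, pm$y), tolerance = 1e-6)
  }
})

test_that("focal loss closed forms and vanishing at confident correct predictions", {
  # single pixel, p_true = 0.5, alpha = 1, gamma = 2: 0.25 ln 2
  p <- array(c(0.5, 0.5), c(1, 1, 2)); y <- matrix(0L, 1, 1)
  expect_equal(focal_loss(p, y, loss_config(alpha = 1, gamma = 2)),
               0.25 * log(2), tolerance = 1e-9)
  p1 <- array(c(1, 0), c(1, 1, 2))
  expect_lt(focal_loss(p1, y, loss_config(alpha = 1, gamma = 2)), 1e-12)
  expect_lt(focal_loss(p1, y, loss_config(alpha = 1, gamma = 0)), 1e-6)
})

test_that("hybrid loss interpolates its endpoint losses monotonically", {
  pm <- random_probmask(8, 8, 6, seed = 42)
  ce <- cross_entropy_loss(pm$p, pm$y)
  fl <- focal_loss(pm$p, pm$y, loss_config(lambda = 0))
  expect_equal(hybrid_loss(pm$p, pm$y, loss_config(lambda = 1)), ce)
  expect_equal(hybrid_loss(pm$p, pm$y, loss_config(lambda = 0)), fl)
  # single-pixel worked example: lambda 0.5, p_true 0.5, alpha 1, gamma 2
  p <- array(c(0.5, 0.5), c(1, 1, 2)); y <- matrix(0L, 1, 1)
  expect_equal(hybrid_loss(p, y, loss_config(lambda = 0.5, alpha = 1, gamma = 2)),
               0.5 * log(2) + 0.5 * 0.25 * log(2), tolerance = 1e-9)
  # continuity/monotonicity in lambda between the endpoints (fl <= ce here)
  lams <- seq(0, 1, by = 0.1)
  vals <- vapply(lams, function(l)
    hybrid_loss(pm$p, pm$y, loss_config(lambda = l)), numeric(1))
  expect_true(all(diff(vals) > -1e-12) || all(diff(vals) < 1e-12))
  expect_error(loss_config(lambda = 1.2), class = "melseg_error_validation")
})

test_that("focal loss never exceeds alpha times cross-entropy", {
  for (s in c(3, 9, 27)) {
    pm <- random_probmask(5, 5, 4, seed = s)
    for (g in c(0, 0.5, 1, 2, 5)) {
      cfg <- loss_config(alpha = 0.25, gamma = g)
      expect_lte(focal_loss(pm$p, pm$y, cfg),
                 cfg$alpha * cross_entropy_loss(pm$p, pm$y) + 1e-12)
    }
  }
})

test_that("confusion matrix counts pixels by (reference, predicted) pair", {
  ref <- matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE)
  cm <- confusion_matrix(pred, ref, 2)
  expect_equal(unname(cm), matrix(c(1, 0, 1, 2), 2, 2))
  expect_equal(sum(cm), 4)
  # identical masks give a diagonal matrix with class pixel counts
  cm2 <- confusion_matrix(ref, ref, 2)
  expect_equal(unname(cm2), diag(c(2, 2)))
  expect_error(confusion_matrix(pred, matrix(0L, 3, 3), 2),
               class = "melseg_error_validation")
})

test_that("segmentation metrics agree with a brute-force pixel tally on random masks", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      ref <- matrix(sample(0:5, 256, TRUE), 16, 16)
      pred <- matrix(sample(0:5, 256, TRUE), 16, 16)
      cm <- confusion_matrix(pred, ref, 6)
      m <- segmentation_metrics(cm)
      b <- brute_metrics(as.vector(pred), as.vector(ref), 6)
      expect_equal(unname(unclass(cm)), unname(b$cm), tolerance = 1e-10)
      expect_equal(m$macro$acc, b$acc, tolerance = 1e-10)
      expect_equal(m$macro$miou, b$miou, tolerance = 1e-10)
      expect_equal(m$per_class$iou, b$iou, tolerance = 1e-10)
      expect_equal(m$per_class$precision, b$precision, tolerance = 1e-10)
      expect_equal(m$per_class$recall, b$recall, tolerance = 1e-10)
      expect_equal(m$per_class$specificity, b$specificity, tolerance = 1e-10)
      expect_equal(m$per_class$f1, b$f1, tolerance = 1e-10)
      expect_equal(m$macro$f1, mean(b$f1, na.rm = TRUE), tolerance = 1e-10)
      expect_equal(m$macro$mean_recall, mean(b$recall, na.rm = TRUE),
                   tolerance = 1e-10)
    }
  })
})

test_that("worked toy confusion matrix reproduces hand-computed metrics", {
  cm <- matrix(c(1, 1, 0, 2), 2, 2, byrow = TRUE)
  m <- segmentation_metrics(cm)
  expect_equal(m$macro$acc, 3 / 4)
  expect_equal(m$per_class$iou, c(0.5, 2 / 3))
  expect_equal(m$macro$miou, mean(c(0.5, 2 / 3)), tolerance = 1e-12)
  expect_error(segmentation_metrics(matrix(0, 3, 3)),
               class = "melseg_error_validation")
  # identity predictions score 1 everywhere
  mi <- segmentation_metrics(diag(c(5, 3, 9)))
  expect_true(all(abs(unlist(mi$macro) - 1) < 1e-12))
})

test_that("per-class F1 from global counts equals Dice from the same counts", {
  withr::with_seed(7, {
    ref <- matrix(sample(0:3, 400, TRUE), 20, 20)
    pred <- matrix(sample(0:3, 400, TRUE), 20, 20)
  })
  cm <- confusion_matrix(pred, ref, 4)
  m <- segmentation_metrics(cm)
  for (c in 0:3) {
    tp <- cm[c + 1, c + 1]
    dice_global <- 2 * tp / (sum(cm[, c + 1]) + sum(cm[c + 1, ]))
    expect_equal(m$per_class$f1[c + 1], dice_global, tolerance = 1e-12)
  }
})

test_that("per-image Dice handles overlap, disjoint and empty cases", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  a[1, 1:2] <- 1L                      # |P| = 2
  b[1, 1:4] <- 1L                      # |R| = 4, overlap 2
  expect_equal(dice_per_image(a, b, 1), 2 * 2 / (2 + 4))
  expect_equal(dice_per_image(a, a, 1), 1)
  d <- matrix(0L, 4, 4); d[4, 4] <- 1L
  expect_equal(dice_per_image(a, d, 1), 0)
  expect_equal(dice_per_image(matrix(0L, 2, 2), matrix(0L, 2, 2), 1), 1)
})

test_that("threshold-sweep AUC equals the pair-counting oracle", {
  # worked example: scores 0.9, 0.8, 0.4, 0.3 with labels 1, 0, 1, 0
  sc <- matrix(c(0.1, 0.2, 0.6, 0.7, 0.9, 0.8, 0.4, 0.3), 4, 2)
  auc <- roc_auc_ovr(sc, c(1L, 0L, 1L, 0L))
  expect_equal(unname(auc[2]), 0.75)
  # perfect separation and uninformative scores
  expect_equal(unname(roc_auc_ovr(cbind(0, c(3, 4, 1, 2)),
                                  c(1L, 1L, 0L, 0L))[2]), 1)
  expect_equal(unname(roc_auc_ovr(cbind(0, rep(0.5, 6)),
                                  c(1L, 0L, 1L, 0L, 1L, 0L))[2]), 0.5)
  # random instances up to 200 pixels, with ties
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      score <- round(stats::runif(n), 2)
      pos <- stats::runif(n) < 0.4
      if (!any(pos) || all(pos)) next
      got <- melseg:::auc_sweep(score, pos)
      expect_equal(got, pair_auc(score, pos), tolerance = 1e-10)
    }
  })
  # a class absent from the reference reports NA, not 0
  auc_na <- roc_auc_ovr(matrix(stats::runif(20), 10, 2), rep(1L, 10))
  expect_true(is.na(auc_na[1]))
})

test_that("AUC sweep agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    score <- stats::runif(150)
    pos <- stats::runif(150) < 0.5
  })
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(pos),
                                        predictor = score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(melseg:::auc_sweep(score, pos), ref, tolerance = 1e-10)
})

test_that("run aggregation returns sample means and standard deviations", {
  r1 <- tibble::tibble(miou = 0.5, acc = 0.9)
  r2 <- tibble::tibble(miou = 0.7, acc = 0.9)
  agg <- aggregate_runs(list(r1, r2))
  expect_equal(agg$mean[agg$metric == "miou"], 0.6)
  expect_equal(agg$sd[agg$metric == "miou"], stats::sd(c(0.5, 0.7)))
  expect_equal(agg$sd[agg$metric == "acc"], 0)
  # permutation invariance
  agg2 <- aggregate_runs(list(r2, r1))
  expect_equal(agg, agg2)
  expect_error(aggregate_runs(list(r1)), class = "melseg_error_validation")
})

test_that("paired t-test matches the closed form and is antisymmetric", {
  b <- c(10, 11, 12)
  a <- b + c(1, 2, 3)                  # differences 1, 2, 3
  got <- paired_t_test(a, b)
  expect_equal(got$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(got$df, 2)
  expect_equal(got$p_value,
               2 * stats::pt(abs(got$t), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p_value, got$p_value)
  # degenerate zero-variance differences raise a typed error
  expect_error(paired_t_test(a, a), class = "melseg_error_degenerate")
  expect_error(paired_t_test(a + 2, a), class = "melseg_error_degenerate")
  expect_error(paired_t_test(1, 2), class = "melseg_error_validation")
})

test_that("metrics reports serialize to flat text and per-class CSV", {
  cm <- confusion_matrix(matrix(c(0L, 1L, 1L, 1L), 2), matrix(c(0L, 0L, 1L, 1L), 2), 2)
  m <- segmentation_metrics(cm)
  base <- withr::local_tempfile()
  write_metrics_report(m, base)
  lines <- readLines(paste0(base, ".txt"))
  expect_true(any(grepl("^miou\t", lines)))
  csv <- utils::read.csv(paste0(base, "_per_class.csv"))
  expect_equal(nrow(csv), 2)
  expect_equal(csv$iou, m$per_class$iou)
  # broom-style accessors
  expect_identical(tidy(m), m$per_class)
  expect_identical(glance(m), m$macro)
})
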