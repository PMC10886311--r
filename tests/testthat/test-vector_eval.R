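test_that("threshold segmentation and confusion counts follow their
           definitions", {
  img <- array(c(0, 200, 0, 200, 0, 200, 0, 200), c(2L, 2L, 2L))
  expect_true(all(threshold_segment(img, 0)))
  expect_false(any(threshold_segment(img, 201)))
  expect_equal(threshold_segment(img, 100), img == 200)

  pred <- array(c(TRUE, TRUE, FALSE, FALSE), c(1L, 2L, 2L))
  truth <- array(c(TRUE, FALSE, TRUE, FALSE), c(1L, 2L, 2L))
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0L)
  inv <- confusion(!truth, truth)
  expect_equal(inv$TP + inv$TN, 0L)
})

test_that("weighted accuracy combines sensitivity and specificity", {
  cc <- structure(list(TP = 5L, FN = 5L, TN = 10L, FP = 0L),
                  class = "confusion_counts")
  expect_equal(weighted_accuracy(cc), 0.1 * 0.5 + 0.9 * 1.0)  # 0.95
  perfect <- structure(list(TP = 3L, FN = 0L, TN = 7L, FP = 0L),
                       class = "confusion_counts")
  expect_equal(weighted_accuracy(perfect), 1.0)
  blind <- structure(list(TP = 0L, FN = 3L, TN = 7L, FP = 0L),
                     class = "confusion_counts")
  expect_equal(weighted_accuracy(blind), 0.9)
  # (0.5, 0.5) weights give balanced accuracy
  expect_equal(weighted_accuracy(cc, 0.5, 0.5), (0.5 + 1) / 2)
  bad <- structure(list(TP = 0L, FN = 0L, TN = 1L, FP = 0L),
                   class = "confusion_counts")
  expect_error(weighted_accuracy(bad), "sensitivity")
})

test_that("accuracy sweep finds a separating threshold on clean images and
           matches direct per-threshold evaluation", {
  img <- array(0, c(2L, 8L, 8L)); truth <- array(FALSE, dim(img))
  img[, 1:4, ] <- 200; truth[, 1:4, ] <- TRUE
  sw <- peak_accuracy_sweep(img, truth, thresholds = c(0, 50, 100, 201))
  expect_equal(sw$best_accuracy, 1.0)
  expect_equal(sw$best_threshold, 50)      # lowest separating threshold
  # truth mask used as its own image over {0, 1}
  sw2 <- peak_accuracy_sweep(1 * truth, truth, thresholds = c(0, 1))
  expect_equal(sw2$best_accuracy, 1.0)
  expect_equal(sw2$best_threshold, 1)
  # histogram sweep equals direct confusion at every grid point
  set.seed(1)
  noisy <- img + array(rnorm(length(img), 0, 80), dim(img))
  grid <- seq(min(noisy), max(noisy), length.out = 33)
  sw3 <- peak_accuracy_sweep(noisy, truth, thresholds = grid)
  direct <- vapply(grid, function(t)
    weighted_accuracy(confusion(noisy >= t, truth)), 1)
  expect_equal(sw3$curve$accuracy, direct, tolerance = 1e-12)
  expect_true(sw3$best_accuracy > 0.5 && sw3$best_accuracy < 1)
  # determinism
  sw4 <- peak_accuracy_sweep(noisy, truth, thresholds = grid)
  expect_identical(sw3$curve, sw4$curve)
})

test_that("strand metrics: straight, planar and semicircular geometries", {
  up <- strand(cbind(z = c(0, 10, 20), y = c(5, 5, 5), x = c(5, 5, 5)),
               radii = c(2, 2, 2))
  m <- strand_metrics(up)
  expect_equal(m$length_um, 20)
  expect_equal(m$z_direction, 1)
  expect_equal(m$inverse_tortuosity, 1)
  expect_equal(m$mean_radius_um, 2)

  flat <- strand(cbind(z = c(0, 0), y = c(0, 3), x = c(0, 4)), radii = c(1, 3))
  mf <- strand_metrics(flat)
  expect_equal(mf$z_direction, 0)
  expect_equal(mf$length_um, 5)
  expect_equal(mf$mean_radius_um, 2)       # trapezoid of (1, 3)

  theta <- seq(0, pi, length.out = 2001)   # semicircle of radius 7
  semi <- strand(cbind(z = 0, y = 7 * sin(theta), x = 7 * cos(theta)),
                 radii = rep(1, length(theta)))
  ms <- strand_metrics(semi)
  expect_equal(ms$inverse_tortuosity, 2 / pi, tolerance = 1e-5)

  expect_error(strand(cbind(0, 0, 0), radii = 1), "n >= 2")
  expect_error(strand(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1, 1)),
               "coincide")
})

test_that("inverse tortuosity is <= 1 with equality only for straight
           strands", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pts <- apply(matrix(rnorm(3 * n), n, 3), 2, cumsum)
    s <- strand(pts, radii = runif(n, 0.5, 2))
    m <- strand_metrics(s)
    expect_lte(m$inverse_tortuosity, 1 + 1e-12)
    expect_gte(m$z_direction, 0); expect_lte(m$z_direction, 1)
  }
  straight <- strand(cbind(0:9, seq(0, 18, length.out = 10),
                           seq(0, 27, length.out = 10)),
                     radii = rep(1, 10))
  expect_equal(strand_metrics(straight)$inverse_tortuosity, 1)
})

test_that("ecdf handles single values, plateaus and duplicates", {
  e1 <- ecdf_steps(5)
  expect_equal(e1$x, 5); expect_equal(e1$p, 1)
  e2 <- ecdf_steps(c(1, 2, 3))
  expect_equal(e2$fun(2), 2 / 3)
  e3 <- ecdf_steps(c(1, 1, 2))
  expect_equal(e3$fun(1), 2 / 3)
  expect_equal(e3$p[length(e3$p)], 1)
  expect_error(ecdf_steps(numeric(0)), "empty")
})

test_that("CDF Pearson r^2: identity gives 1, hand-computed grid matches,
           and near-linear CDFs correlate despite different ranges", {
  set.seed(3)
  a <- rnorm(40)
  expect_equal(cdf_pearson_r2(a, a), 1)
  # hand-computed: CDFs of two tiny samples on an explicit grid
  x <- c(1, 2, 3); y <- c(2, 3, 4); grid <- c(1, 2, 3, 4, 5)
  fa <- c(1, 2, 3, 3, 3) / 3; fb <- c(0, 1, 2, 3, 3) / 3
  expect_equal(cdf_pearson_r2(x, y, grid), cor(fa, fb)^2, tolerance = 1e-12)
  # documented limitation: overlapping uniforms on different ranges still
  # correlate strongly (why the K-S test is reported alongside)
  u1 <- runif(400, 0, 1); u2 <- runif(400, 0.3, 1.3)
  expect_gt(cdf_pearson_r2(u1, u2), 0.9)
  expect_error(cdf_pearson_r2(c(1, 1), c(5, 5), grid = c(2, 3)), "constant")
})

test_that("two-sample K-S statistic matches the ECDF-gap definition", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 101:105)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic, 0.5)
  # brute-force oracle: sup gap over the pooled support
  ks_oracle <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  set.seed(4)
  for (i in 1:8) {
    a <- sample(1:20, sample(3:8, 1), replace = TRUE)
    b <- sample(1:20, sample(3:8, 1), replace = TRUE)
    expect_equal(ks_two_sample(a, b)$statistic, ks_oracle(a, b),
                 tolerance = 1e-12)
  }
  # D is invariant under strictly monotone transforms
  a <- rnorm(30); b <- rnorm(30, 1)
  expect_equal(ks_two_sample(a, b)$statistic,
               ks_two_sample(exp(a), exp(b))$statistic)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})
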