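test_that("standardizer z-scores with the population denominator", {
  m <- matrix(c(2, 4, 6), ncol = 1)
  s <- fit_standardizer(m)
  z <- apply_standardizer(s, m)
  expect_equal(unname(z[, 1]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  const <- cbind(a = c(1, 1, 1), b = c(2, 4, 6))
  z2 <- apply_standardizer(fit_standardizer(const), const)
  expect_equal(unname(z2[, "a"]), c(0, 0, 0))

  set.seed(1)
  big <- matrix(rnorm(200), 20, 10)
  zb <- apply_standardizer(fit_standardizer(big), big)
  expect_true(all(abs(colMeans(zb)) < 1e-10))
  expect_true(all(abs(sqrt(colMeans(zb^2)) - 1) < 1e-10))

  expect_error(fit_standardizer(matrix(1, 1, 2)), ">= 2 samples")
})

test_that("PCA loadings are orthonormal with decreasing explained variance", {
  set.seed(2)
  x <- matrix(rnorm(120), 20, 6)
  m <- fit_pca(x, k_or_variance = 6)
  gram <- crossprod(m$loadings)
  expect_equal(gram, diag(6), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_equal(sum(m$explained_variance), 1, tolerance = 1e-10)
  expect_error(fit_pca(x, 10), "exceeds")
})

test_that("variance-fraction selection keeps the smallest sufficient k", {
  set.seed(3)
  # strong 2-D structure in 5 dims
  z <- matrix(rnorm(200), 100, 2)
  x <- cbind(z %*% matrix(c(5, 0, 0, 3), 2), matrix(rnorm(300, sd = 0.05),
                                                    100, 3))
  m <- fit_pca(x, 0.95)
  expect_equal(m$k, 2)
})

test_that("PCA reconstruction error matches a brute-force residual oracle", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(60), 10, 6)
    for (k in c(2, 4, 6)) {
      m <- fit_pca(x, k)
      got <- pca_reconstruction_error(m, x)
      # independent oracle: residual after explicit projection onto the
      # loading subspace
      centered <- sweep(x, 2, m$center)
      proj <- centered %*% m$loadings %*% t(m$loadings)
      expect_equal(unname(got), rowSums((centered - proj)^2),
                   tolerance = 1e-8)
    }
    expect_true(all(pca_reconstruction_error(fit_pca(x, 6), x) <= 1e-8))
  }
  x <- matrix(rnorm(60), 10, 6)
  m <- fit_pca(x, 3)
  # a sample inside the retained span reconstructs exactly
  inside <- matrix(m$center + m$loadings[, 1] * 2.5, 1)
  expect_lt(pca_reconstruction_error(m, inside), 1e-16)
  expect_error(pca_reconstruction_error(m, matrix(0, 1, 3)), "mismatch")
})

test_that("one-class SVM separates a far point from a tight cluster", {
  set.seed(5)
  x <- rbind(matrix(rnorm(240), 60, 4), rep(6, 4))
  rownames(x) <- sprintf("s%03d", 1:61)
  z <- apply_standardizer(fit_standardizer(x), x)

  # a kernel width small enough not to saturate puts the far point first;
  # under the variance-scaled default all distant points tie near the
  # boundary constant and only the above-median direction is guaranteed
  m <- fit_ocsvm(z, gamma = 0.02)
  sc <- anomaly_scores(m, z)
  expect_equal(names(which.max(sc)), "s061")

  m_def <- fit_ocsvm(z)
  sc_def <- anomaly_scores(m_def, z)
  expect_gt(sc_def["s061"], stats::median(sc_def[1:60]))

  # duplicated inlier rows get equal scores
  dup <- rbind(z, z[1, , drop = FALSE])
  expect_lt(abs(anomaly_scores(m, dup)[62] - sc[1]), 1e-9)

  nrm <- normalize_scores(sc)
  expect_true(all(nrm >= 0 & nrm <= 1))
  expect_equal(max(nrm), 1)

  expect_error(fit_ocsvm(z, kernel = "poly"))

  # linear kernel: a positive cluster with an outlier at the origin
  set.seed(6)
  xl <- rbind(matrix(rnorm(240, mean = 5), 60, 4), rep(0, 4))
  rownames(xl) <- sprintf("s%03d", 1:61)
  m_lin <- fit_ocsvm(xl, kernel = "linear")
  expect_equal(names(which.max(anomaly_scores(m_lin, xl))), "s061")
})

test_that("isolation forest isolates planted outliers and is seeded", {
  cloud <- make_cloud(n_in = 80, n_out = 1, p = 6, shift = 8, seed = 6)
  m <- fit_iforest(cloud$x, seed = 3)
  sc <- anomaly_scores(m, cloud$x)
  expect_equal(names(which.max(sc)), cloud$outliers)

  m2 <- fit_iforest(cloud$x, seed = 3)
  expect_identical(anomaly_scores(m2, cloud$x), sc)

  # different seeds: stable ranking on the planted-anomaly fixture
  m3 <- fit_iforest(cloud$x, seed = 99)
  expect_gt(cor(sc, anomaly_scores(m3, cloud$x), method = "spearman"), 0.9)

  expect_error(fit_iforest(cloud$x, n_trees = 0), "n_trees")
})

test_that("autoencoder training reduces loss and flags planted outliers", {
  cloud <- make_cloud(n_in = 80, n_out = 5, p = 6, shift = 8, seed = 7)
  z <- apply_standardizer(fit_standardizer(cloud$x), cloud$x)
  m <- fit_autoencoder(z, epochs = 50, seed = 2)
  expect_lt(m$training_loss[50], m$training_loss[1])

  sset <- score_autoencoder(m, z)
  expect_outliers_above_median(sset, cloud$inliers, cloud$outliers)
  expect_gt(mean(sset$raw[cloud$outliers]), mean(sset$raw[cloud$inliers]))

  m2 <- fit_autoencoder(z, epochs = 50, seed = 2)
  expect_identical(anomaly_scores(m2, z), sset$raw)

  expect_error(fit_autoencoder(z, hidden = c(8, 10, 8)), "bottleneck")
})

test_that("every model gives planted outliers a score above the inlier median", {
  cloud <- make_cloud(n_in = 100, n_out = 5, p = 6, shift = 8, seed = 8)
  z <- apply_standardizer(fit_standardizer(cloud$x), cloud$x)
  models <- list(
    pca = fit_pca(z, 3),
    ocsvm = fit_ocsvm(z),
    iforest = fit_iforest(z, seed = 1),
    autoencoder = fit_autoencoder(z, seed = 1))
  for (name in names(models)) {
    sset <- anomaly_score_set(name, anomaly_scores(models[[name]], z))
    expect_outliers_above_median(sset, cloud$inliers, cloud$outliers)
  }
})

test_that("min-max normalization is order-preserving with degenerate fallback", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_scores(c(5, 5, 5)), c(0, 0, 0))
  set.seed(9)
  raw <- rnorm(50)
  expect_equal(order(normalize_scores(raw)), order(raw))
  expect_error(normalize_scores(numeric(0)), "empty")
})

test_that("percentile thresholding labels strictly-above samples as outliers", {
  s <- anomaly_score_set("pca", stats::setNames(1:100, paste0("s", 1:100)))
  thr <- percentile_threshold(s, 95)
  expect_equal(sum(thr$labels == -1L), 5)
  expect_true(all(s$normalized[thr$labels == -1L] > thr$threshold))
  expect_true(all(s$normalized[thr$labels == 1L] <= thr$threshold))

  flat <- anomaly_score_set("pca", rep(3, 50))
  expect_equal(sum(percentile_threshold(flat, 95)$labels == -1L), 0)

  set.seed(10)
  big <- anomaly_score_set("pca", rnorm(1000))
  frac <- percentile_threshold(big, 95)$flagged_fraction
  expect_equal(frac, 0.05, tolerance = 0.1)

  expect_error(percentile_threshold(s, 0), "percentile")
  expect_error(percentile_threshold(s, 100), "percentile")
  expect_warning(percentile_threshold(anomaly_score_set("pca", 1:5), 95),
                 "fewer than 20")
})

test_that("score summaries report the comparison-table row", {
  s <- anomaly_score_set("ocsvm", c(a = 0, b = 0.5, c = 1))
  sm <- suppressWarnings(summarize_scores(s))
  expect_equal(sm$mean_score, 0.5)
  expect_equal(sm$median_score, 0.5)

  set.seed(11)
  u <- anomaly_score_set("iforest", runif(10000))
  sm2 <- summarize_scores(u, 95)
  expect_equal(sm2$mean_score, 0.5, tolerance = 0.02)
  thr <- percentile_threshold(u, 95)
  expect_equal(sm2$outlier_pct / 100, mean(u$normalized > thr$threshold))
})

test_that("score tables expose one labeled row per sample", {
  s <- anomaly_score_set("pca", stats::setNames(runif(30), paste0("s", 1:30)))
  tab <- score_table(percentile_threshold(s, 90))
  expect_equal(nrow(tab), 30)
  expect_named(tab, c("sample_id", "model", "raw_score", "normalized_score",
                      "threshold", "label"))
  expect_true(all(tab$label %in% c(-1L, 1L)))
})
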