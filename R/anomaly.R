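# One-class anomaly models under a common contract:
# every fitted model answers anomaly_scores(model, matrix) with a raw score
# per sample where HIGHER = MORE ANOMALOUS, whatever the model's native
# sign convention.

#' Fit a feature standardizer (z-scoring)
#'
#' Learns per-feature mean and standard deviation on training data. The
#' standard deviation uses the 1/n (population) denominator, so a column
#' (2, 4, 6) maps to approximately (-1.2247, 0, 1.2247). Features with
#' sd < 1e-12 are recorded as constant and mapped to 0 on application,
#' never divided by.
#'
#' @param train numeric matrix (>= 2 samples).
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(train) {
  if (nrow(train) < 2) stop("need >= 2 samples to standardize", call. = FALSE)
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, mu)^2))
  constant <- sd_pop < 1e-12
  structure(list(mean = mu, sd = ifelse(constant, 1, sd_pop),
                 constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#' @param s a `standardizer`.
#' @param matrix numeric matrix over the same features.
#' @export
apply_standardizer <- function(s, matrix) {
  stopifnot(inherits(s, "standardizer"))
  if (ncol(matrix) != length(s$mean)) {
    stop("feature count mismatch between standardizer and matrix",
         call. = FALSE)
  }
  z <- sweep(sweep(matrix, 2, s$mean), 2, s$sd, "/")
  z[, s$constant] <- 0
  z
}

#' Fit PCA on a standardized feature matrix
#'
#' Components are ranked by decreasing eigenvalue. `k_or_variance` is
#' either an integer component count or a fraction in (0, 1), in which case
#' the smallest k whose cumulative explained variance reaches it is kept.
#'
#' @param matrix standardized numeric matrix (n >= 2).
#' @param k_or_variance integer k, or a variance fraction (default 0.95).
#' @return Object of class `pca_model` with orthonormal loadings, the
#'   training means and per-component explained variance; it is also an
#'   anomaly scorer whose score is the per-sample reconstruction error.
#' @export
fit_pca <- function(matrix, k_or_variance = 0.95) {
  if (nrow(matrix) < 2) stop("need >= 2 samples for PCA", call. = FALSE)
  pr <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  k_max <- sum(ev > 1e-12)
  if (k_or_variance >= 1) {
    k <- as.integer(k_or_variance)
    if (k > min(nrow(matrix) - 1, ncol(matrix))) {
      stop("k exceeds min(n - 1, p)", call. = FALSE)
    }
    k <- min(k, ncol(pr$rotation))
  } else {
    frac <- cumsum(ev) / sum(ev)
    k <- which(frac >= k_or_variance)[1]
  }
  structure(list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 center = pr$center,
                 explained_variance = ev[seq_len(k)] / sum(ev),
                 eigenvalues = ev[seq_len(k)],
                 k = k, k_max = k_max),
            class = c("pca_model", "anomaly_model"))
}

#' Project a matrix onto retained principal components
#' @param model a `pca_model`.
#' @param matrix matrix over the training feature space.
#' @export
pca_transform <- function(model, matrix) {
  stopifnot(inherits(model, "pca_model"))
  if (ncol(matrix) != length(model$center)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  sweep(matrix, 2, model$center) %*% model$loadings
}

#' Per-sample squared PCA reconstruction error
#'
#' Projects each sample onto the retained components, reconstructs, and
#' returns the squared residual norm. With k = p the error is ~0 for every
#' sample.
#'
#' @param model a `pca_model`.
#' @param matrix matrix over the training feature space.
#' @export
pca_reconstruction_error <- function(model, matrix) {
  z <- pca_transform(model, matrix)
  recon <- sweep(z %*% t(model$loadings), 2, model$center, "+")
  err <- rowSums((matrix - recon)^2)
  stats::setNames(err, rownames(matrix))
}

# ---- common scorer contract -------------------------------------------------

#' Raw anomaly scores from a fitted one-class model
#'
#' Generic over the four model classes (`pca_model`, `ocsvm_model`,
#' `iforest_model`, `autoencoder_model`); always returns one finite score
#' per row with higher = more anomalous.
#'
#' @param model a fitted anomaly model.
#' @param matrix matrix over the model's feature space.
#' @export
anomaly_scores <- function(model, matrix) UseMethod("anomaly_scores")

#' @export
anomaly_scores.pca_model <- function(model, matrix) {
  pca_reconstruction_error(model, matrix)
}

#' Fit a one-class SVM and score a matrix
#'
#' Wraps the nu-parameterized one-class SVM; the raw anomaly score is the
#' negated decision value (signed distance from the learned boundary), so
#' samples outside the boundary score highest.
#'
#' @param train numeric training matrix (n >= 2).
#' @param kernel `"linear"` or `"rbf"`.
#' @param nu upper bound on the training outlier fraction (default 0.05).
#' @param gamma RBF kernel width; default `NULL` uses the variance-scaled
#'   convention `1 / (p * var(train))`, which keeps the kernel informative
#'   whatever the scale of the feature space (a fixed `1/p` saturates when
#'   features have large variance, e.g. on PCA scores).
#' @return Object of class `ocsvm_model`.
#' @export
fit_ocsvm <- function(train, kernel = c("rbf", "linear"), nu = 0.05,
                      gamma = NULL) {
  if (nrow(train) < 2) stop("need >= 2 samples", call. = FALSE)
  kernel <- match.arg(kernel)
  if (is.null(gamma)) {
    v <- mean(apply(train, 2, function(col) mean((col - mean(col))^2)))
    gamma <- 1 / (ncol(train) * max(v, .Machine$double.eps))
  }
  fit <- e1071::svm(train, y = NULL, type = "one-classification",
                    kernel = switch(kernel, rbf = "radial", linear = "linear"),
                    nu = nu, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, kernel = kernel, nu = nu, p = ncol(train)),
            class = c("ocsvm_model", "anomaly_model"))
}

#' @export
anomaly_scores.ocsvm_model <- function(model, matrix) {
  if (ncol(matrix) != model$p) stop("feature dimension mismatch", call. = FALSE)
  pred <- stats::predict(model$fit, matrix, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  stats::setNames(-dv, rownames(matrix))
}

#' Fit and score in one call, returning a score set
#'
#' Convenience wrappers matching the fit-then-score contract of each model.
#'
#' @param train training matrix.
#' @param ... passed to the fitter.
#' @return An [anomaly_score_set] over the training samples.
#' @name fit_score
NULL

#' @rdname fit_score
#' @export
fit_score_ocsvm <- function(train, ...) {
  m <- fit_ocsvm(train, ...)
  anomaly_score_set("ocsvm", anomaly_scores(m, train))
}

#' @rdname fit_score
#' @param seed integer seed for the tree ensemble.
#' @export
fit_score_iforest <- function(train, seed = 1, ...) {
  m <- fit_iforest(train, seed = seed, ...)
  anomaly_score_set("iforest", anomaly_scores(m, train))
}

# ---- score sets, normalization, thresholding --------------------------------

#' Bundle raw anomaly scores with their min-max normalization
#'
#' @param model_name one of `"autoencoder"`, `"ocsvm"`, `"iforest"`,
#'   `"pca"`.
#' @param raw named numeric vector of raw scores (higher = more anomalous).
#' @return Object of class `anomaly_score_set` with `raw` and `normalized`
#'   (min-max over the scored set, in `[0, 1]`).
#' @export
anomaly_score_set <- function(model_name, raw) {
  model_name <- match.arg(model_name,
                          c("autoencoder", "ocsvm", "iforest", "pca"))
  if (!length(raw)) stop("empty score vector", call. = FALSE)
  if (any(!is.finite(raw))) stop("non-finite anomaly score", call. = FALSE)
  structure(list(model_name = model_name, raw = raw,
                 normalized = normalize_scores(raw)),
            class = "anomaly_score_set")
}

#' Min-max normalize scores to [0, 1]
#'
#' Order-preserving; a constant vector maps to all zeros.
#' @param raw numeric vector (length >= 1).
#' @export
normalize_scores <- function(raw) {
  if (!length(raw)) stop("empty score vector", call. = FALSE)
  rng <- range(raw)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(stats::setNames(rep(0, length(raw)), names(raw)))
  }
  (raw - rng[1]) / diff(rng)
}

#' Threshold normalized anomaly scores at a percentile
#'
#' The threshold is the given percentile of the normalized scores (linear
#' interpolation between order statistics, i.e. `quantile(type = 7)`);
#' samples strictly above it are labeled outliers (-1), the rest inliers
#' (+1). With the 95th percentile this flags roughly 5% of the scored set.
#'
#' @param scores an [anomaly_score_set].
#' @param percentile in (0, 100); default 95. Below 20 samples a warning is
#'   issued (a high percentile is poorly determined).
#' @return Object of class `thresholded_result` with the threshold, labels
#'   and flagged fraction.
#' @export
percentile_threshold <- function(scores, percentile = 95) {
  stopifnot(inherits(scores, "anomaly_score_set"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  x <- scores$normalized
  if (length(x) < 20) {
    warning("fewer than 20 samples; percentile threshold is coarse",
            call. = FALSE)
  }
  thr <- unname(stats::quantile(x, percentile / 100, type = 7))
  labels <- ifelse(x > thr, -1L, 1L)
  structure(list(scores = scores, percentile = percentile, threshold = thr,
                 labels = stats::setNames(labels, names(x)),
                 flagged_fraction = mean(labels == -1L)),
            class = "thresholded_result")
}

#' Score-distribution summary (mean, median, threshold, outlier %)
#'
#' One row of the standard comparison table for a model's normalized
#' scores: mean, median, the percentile threshold, and the percentage of
#' samples flagged above it.
#'
#' @param scores an [anomaly_score_set].
#' @param percentile threshold percentile (default 95).
#' @export
summarize_scores <- function(scores, percentile = 95) {
  stopifnot(inherits(scores, "anomaly_score_set"))
  thr <- percentile_threshold(scores, percentile)
  data.frame(model = scores$model_name,
             mean_score = mean(scores$normalized),
             median_score = stats::median(scores$normalized),
             threshold = thr$threshold,
             outlier_pct = 100 * thr$flagged_fraction,
             stringsAsFactors = FALSE)
}

#' Score table in long TSV-ready form
#' @param result a `thresholded_result`.
#' @export
score_table <- function(result) {
  stopifnot(inherits(result, "thresholded_result"))
  s <- result$scores
  data.frame(sample_id = names(s$raw),
             model = s$model_name,
             raw_score = unname(s$raw),
             normalized_score = unname(s$normalized),
             threshold = result$threshold,
             label = unname(result$labels),
             stringsAsFactors = FALSE)
}
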