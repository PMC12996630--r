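# End-to-end pipeline: features -> standardize -> PCA -> one-class model
# -> normalized scores -> percentile threshold -> importance -> DPAS.

#' Fit the full one-class scoring chain on a feature matrix
#'
#' Standardizes, optionally PCA-reduces, and fits the chosen one-class
#' model. The returned object scores *raw* feature matrices through the
#' whole chain, so feature attributions computed against it are expressed
#' in the original, named feature space.
#'
#' @param x raw (unstandardized) feature matrix.
#' @param model `"autoencoder"`, `"ocsvm"`, `"iforest"` or `"pca"`.
#' @param pca_variance variance fraction or integer k for the PCA step;
#'   `NULL` skips PCA; the default `"auto"` uses the smallest k explaining
#'   95% of variance for the SVM and the autoencoder but skips PCA for the
#'   isolation forest — axis-aligned random splits lose the anomaly signal
#'   when it is rotated into many retained noise components, and tree
#'   ensembles need no decorrelation. For `model = "pca"` the reduction
#'   itself is the scorer and this controls its retained components.
#' @param seed integer seed for the stochastic fitters.
#' @param ... passed to the model fitter ([fit_ocsvm()], [fit_iforest()],
#'   [fit_autoencoder()]).
#' @return Object of class `dpas_model`.
#' @export
fit_dpas_model <- function(x, model = c("autoencoder", "ocsvm", "iforest", "pca"),
                           pca_variance = "auto", seed = 1, ...) {
  model <- match.arg(model)
  if (identical(pca_variance, "auto")) {
    pca_variance <- if (model == "iforest") NULL else 0.95
  }
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  pca <- NULL
  if (model == "pca") {
    inner <- fit_pca(z, if (is.null(pca_variance)) 0.95 else pca_variance)
  } else {
    if (!is.null(pca_variance)) {
      pca <- fit_pca(z, pca_variance)
      z <- pca_transform(pca, z)
    }
    inner <- switch(model,
                    autoencoder = fit_autoencoder(z, seed = seed, ...),
                    ocsvm = fit_ocsvm(z, ...),
                    iforest = fit_iforest(z, seed = seed, ...))
  }
  structure(list(model_name = model, standardizer = std, pca = pca,
                 inner = inner, seed = seed,
                 feature_names = colnames(x)),
            class = c("dpas_model", "anomaly_model"))
}

#' @export
anomaly_scores.dpas_model <- function(model, matrix) {
  if (!identical(colnames(matrix), model$feature_names)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  z <- apply_standardizer(model$standardizer, matrix)
  if (!is.null(model$pca)) z <- pca_transform(model$pca, z)
  anomaly_scores(model$inner, z)
}

#' Score a feature matrix with a fitted pipeline model
#' @param model a `dpas_model`.
#' @param x raw feature matrix with the training columns.
#' @return An [anomaly_score_set].
#' @export
score_dpas_model <- function(model, x) {
  anomaly_score_set(model$model_name, anomaly_scores(model, x))
}

#' Run the whole anomaly-scoring and ranking pipeline on a peptide set
#'
#' Featurizes the peptides, fits the chosen one-class model on the
#' standardized (optionally PCA-reduced) features, normalizes the anomaly
#' scores, thresholds them at a percentile, computes permutation feature
#' importance against the fitted chain, and fuses score and importance
#' into the DPAS ranking.
#'
#' @param set a [peptide_set].
#' @param model one-class model name (default `"autoencoder"`).
#' @param config [feature_config()].
#' @param motif_block optional motif block for the feature matrix.
#' @param pca_variance PCA setting (see [fit_dpas_model()]).
#' @param percentile outlier threshold percentile (default 95).
#' @param weights [dpas_weights()].
#' @param n_perm permutation rounds for importance (default 3).
#' @param seed integer seed.
#' @param ... passed to the model fitter.
#' @return List with `features`, `model`, `scores`, `thresholded`,
#'   `summary`, `importance`, `top_features` and `ranking`.
#' @export
run_dpas <- function(set, model = "autoencoder", config = feature_config(),
                     motif_block = NULL, pca_variance = "auto",
                     percentile = 95, weights = dpas_weights(),
                     n_perm = 3, seed = 1, ...) {
  x <- assemble_feature_matrix(set, config, motif_block = motif_block)
  fit <- fit_dpas_model(x, model = model, pca_variance = pca_variance,
                        seed = seed, ...)
  scores <- score_dpas_model(fit, x)
  thr <- percentile_threshold(scores, percentile)
  imp <- feature_importance(fit, x, n_perm = n_perm, seed = seed + 1L)
  top <- top_k_features(imp$global_importance, k = min(weights$top_k, ncol(x)))
  iterm <- importance_term(imp$attributions, top)
  ranking <- dpas_score(scores$normalized, iterm, weights)
  list(features = x, model = fit, scores = scores, thresholded = thr,
       summary = summarize_scores(scores, percentile),
       importance = imp, top_features = top, ranking = ranking)
}
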