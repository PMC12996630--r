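# Feature attribution and the Disease Peptide Anomaly Score (DPAS):
#   DPAS = alpha * normalized anomaly score + beta * importance term
# with user-set weights alpha, beta >= 0, alpha + beta > 0.

#' Model-agnostic permutation feature importance
#'
#' For each feature, each of `n_perm` rounds replaces the column by a
#' permutation of its background values (the scored matrix itself) and
#' records, per sample, the absolute change of the model's raw anomaly
#' score. The attribution is the mean absolute change across rounds; the
#' global importance of a feature is the mean attribution over samples.
#' A feature the model ignores, or one that is constant across the
#' background, receives (near-)zero attribution. Seeded and deterministic.
#'
#' @param model any fitted anomaly model (answers [anomaly_scores()]).
#' @param matrix numeric matrix the model can score.
#' @param n_perm permutation rounds per feature (default 5).
#' @param seed integer seed.
#' @return List with `attributions` (samples x features matrix) and
#'   `global_importance` (named per-feature vector).
#' @export
feature_importance <- function(model, matrix, n_perm = 5, seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  base <- anomaly_scores(model, matrix)
  n <- nrow(matrix)
  p <- ncol(matrix)
  attr_mat <- matrix(0, n, p, dimnames = dimnames(matrix))
  with_seed(seed, {
    for (j in seq_len(p)) {
      acc <- numeric(n)
      for (r in seq_len(n_perm)) {
        perturbed <- matrix
        perturbed[, j] <- matrix[sample.int(n), j]
        acc <- acc + abs(anomaly_scores(model, perturbed) - base)
      }
      attr_mat[, j] <- acc / n_perm
    }
  })
  list(attributions = attr_mat,
       global_importance = colMeans(attr_mat))
}

#' Top-k features by global importance
#'
#' @param global_importance named numeric vector.
#' @param k number of features (default 3); ties break by feature-name
#'   order.
#' @return Character vector of k feature names in decreasing importance.
#' @export
top_k_features <- function(global_importance, k = 3) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k > length(global_importance)) {
    stop("`k` exceeds the number of features", call. = FALSE)
  }
  ord <- order(-global_importance, names(global_importance))
  names(global_importance)[ord][seq_len(k)]
}

#' Per-sample importance term over selected features
#'
#' Mean absolute attribution of each sample over the selected features,
#' min-max normalized across samples to `[0, 1]` (so the term is invariant
#' to a positive rescaling of all attributions).
#'
#' @param attributions samples x features attribution matrix.
#' @param features non-empty character vector of feature names to use.
#' @return Named per-sample vector in `[0, 1]`.
#' @export
importance_term <- function(attributions, features) {
  if (!length(features)) stop("empty feature list", call. = FALSE)
  missing <- setdiff(features, colnames(attributions))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_sample <- rowMeans(abs(attributions[, features, drop = FALSE]))
  normalize_scores(per_sample)
}

#' DPAS weights
#' @param alpha weight of the normalized anomaly score (>= 0).
#' @param beta weight of the importance term (>= 0); `alpha + beta > 0`.
#' @param top_k number of globally important features feeding the
#'   importance term (default 3).
#' @export
dpas_weights <- function(alpha = 0.5, beta = 0.5, top_k = 3) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("need alpha, beta >= 0 with alpha + beta > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, top_k = top_k),
            class = "dpas_weights")
}

#' Compute DPAS and rank peptides
#'
#' `dpas = alpha * normalized_error + beta * importance_term`, exactly.
#' Ranks are dense, 1-based, by decreasing DPAS; ties break
#' deterministically by sample id.
#'
#' @param normalized_error named per-sample vector in `[0, 1]`.
#' @param importance_term named per-sample vector in `[0, 1]`, same
#'   samples.
#' @param weights a [dpas_weights].
#' @return Data frame of class `dpas_ranking` with columns `sample_id`,
#'   `normalized_error`, `importance_term`, `dpas`, `rank`, ordered by
#'   rank.
#' @export
dpas_score <- function(normalized_error, importance_term,
                       weights = dpas_weights()) {
  stopifnot(inherits(weights, "dpas_weights"))
  if (length(normalized_error) != length(importance_term)) {
    stop("score and importance vectors differ in length", call. = FALSE)
  }
  ids <- names(normalized_error)
  if (is.null(ids)) ids <- as.character(seq_along(normalized_error))
  if (!is.null(names(importance_term))) {
    if (!setequal(ids, names(importance_term))) {
      stop("sample ids of the two terms disagree", call. = FALSE)
    }
    importance_term <- importance_term[ids]
  }
  dpas <- weights$alpha * unname(normalized_error) +
    weights$beta * unname(importance_term)
  ord <- order(-dpas, ids)
  # dense rank: equal dpas -> equal rank
  sorted_d <- dpas[ord]
  dense <- cumsum(c(1L, diff(sorted_d) != 0))
  rank <- integer(length(dpas))
  rank[ord] <- dense
  out <- data.frame(sample_id = ids,
                    normalized_error = unname(normalized_error),
                    importance_term = unname(importance_term),
                    dpas = dpas, rank = rank,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  class(out) <- c("dpas_ranking", "data.frame")
  out
}

#' Select the top-ranked peptides as an exportable set
#'
#' @param ranking a `dpas_ranking`.
#' @param set the [peptide_set] that was scored.
#' @param n how many top peptides (default 15).
#' @return A [peptide_set] of the n top peptides in rank (then id) order,
#'   ready for FASTA export and external annotation.
#' @export
select_top <- function(ranking, set, n = 15) {
  stopifnot(inherits(ranking, "dpas_ranking"), inherits(set, "peptide_set"))
  if (n > nrow(ranking)) {
    stop("`n` exceeds the number of ranked peptides", call. = FALSE)
  }
  top_ids <- ranking$sample_id[seq_len(n)]
  rows <- set[match(top_ids, set$id), , drop = FALSE]
  if (any(is.na(rows$id))) {
    stop("ranking references peptides absent from the set", call. = FALSE)
  }
  peptide_set(rows$id, rows$raw_sequence,
              source = paste0("top-", n, " by DPAS"))
}
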