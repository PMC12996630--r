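# Shared fixtures, all generated in code under fixed seeds.

# random valid peptide of given length
random_sequence <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(dpas::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# correlated low-rank Gaussian cloud with planted far outliers: the
# canonical numeric fixture for the anomaly scorers
make_cloud <- function(n_in = 100, n_out = 5, p = 6, rank = 3, shift = 8,
                       seed = 1) {
  set.seed(seed)
  basis <- matrix(rnorm(rank * p), rank, p)
  inliers <- matrix(rnorm(n_in * rank), n_in, rank) %*% basis +
    matrix(rnorm(n_in * p, sd = 0.1), n_in, p)
  outliers <- matrix(rnorm(n_out * p), n_out, p) + shift
  x <- rbind(inliers, outliers)
  rownames(x) <- sprintf("s%03d", seq_len(n_in + n_out))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, inliers = rownames(x)[seq_len(n_in)],
       outliers = rownames(x)[n_in + seq_len(n_out)])
}

expect_outliers_above_median <- function(score_set, inlier_ids, outlier_ids) {
  med <- stats::median(score_set$normalized[inlier_ids])
  expect_true(all(score_set$normalized[outlier_ids] > med))
}
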