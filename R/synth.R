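# Seeded synthetic peptide sets with planted outliers, column-permutation
# synthetic negatives, and the binary-classification validation experiment
# for positive-only models.

#' Specification of a synthetic peptide dataset
#'
#' Inliers are drawn residue-by-residue from a biased letter-frequency
#' vector, with a short motif planted at a configurable probability;
#' outliers are drawn from a divergent composition concentrated on a small
#' set of residues. The default effect size (inlier composition spread over
#' all 20 letters vs outlier mass confined to C/W/H/M/P) is deliberately
#' large: the fixture exists to test recovery, not to calibrate power.
#'
#' @param n_inliers,n_outliers record counts (>= 0).
#' @param length_range integer (min, max) peptide length, min >= 2.
#' @param inlier_motifs list of [motif] objects planted into inliers.
#' @param plant_probability probability an inlier receives each motif.
#' @param inlier_composition,outlier_composition named 20-letter frequency
#'   vectors summing to 1.
#' @param seed integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_inliers = 100, n_outliers = 5,
                           length_range = c(8L, 15L),
                           inlier_motifs = list(motif("m_STP", "[ST]-P")),
                           plant_probability = 0.5,
                           inlier_composition = default_inlier_composition(),
                           outlier_composition = default_outlier_composition(),
                           seed = 42) {
  check_composition <- function(x, what) {
    if (!setequal(names(x), AA_ALPHABET) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-8) {
      stop(what, " must be a 20-letter frequency vector summing to 1",
           call. = FALSE)
    }
  }
  check_composition(inlier_composition, "inlier_composition")
  check_composition(outlier_composition, "outlier_composition")
  if (length_range[1] < 2) stop("minimum length must be >= 2", call. = FALSE)
  structure(list(n_inliers = n_inliers, n_outliers = n_outliers,
                 length_range = as.integer(length_range),
                 inlier_motifs = inlier_motifs,
                 plant_probability = plant_probability,
                 inlier_composition = inlier_composition[AA_ALPHABET],
                 outlier_composition = outlier_composition[AA_ALPHABET],
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default inlier letter frequencies (broad, natural-like bias)
#' @export
default_inlier_composition <- function() {
  c(A = 0.09, C = 0.02, D = 0.05, E = 0.07, F = 0.04, G = 0.07, H = 0.02,
    I = 0.05, K = 0.06, L = 0.09, M = 0.02, N = 0.04, P = 0.05, Q = 0.04,
    R = 0.05, S = 0.08, T = 0.06, V = 0.07, W = 0.01, Y = 0.02)
}

#' Default outlier letter frequencies (mass confined to five residues)
#' @export
default_outlier_composition <- function() {
  c(A = 0, C = 0.30, D = 0, E = 0, F = 0, G = 0, H = 0.20, I = 0, K = 0,
    L = 0, M = 0.15, N = 0, P = 0.10, Q = 0, R = 0, S = 0, T = 0, V = 0,
    W = 0.25, Y = 0)
}

sample_peptide <- function(len, composition) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = composition),
        collapse = "")
}

plant_motif_instance <- function(sequence, m) {
  # realize a concrete match of the pattern and splice it at a random start
  site <- switch(m$pattern,
                 "[ST]-P" = paste0(sample(c("S", "T"), 1), "P"),
                 prosite_example_match(m))
  pos <- sample.int(nchar(sequence) - nchar(site) + 1, 1)
  paste0(substring(sequence, 1, pos - 1), site,
         substring(sequence, pos + nchar(site)))
}

# a concrete sequence matching a compiled pattern, built token-wise
prosite_example_match <- function(m) {
  regex <- m$regex
  regex <- sub("^\\^", "", sub("\\$$", "", regex))
  out <- character(0)
  i <- 1
  chars <- strsplit(regex, "")[[1]]
  emit <- function(tok) {
    if (tok == ".") sample(AA_ALPHABET, 1)
    else if (startsWith(tok, "[^")) {
      setdiff(AA_ALPHABET, strsplit(substr(tok, 3, nchar(tok) - 1), "")[[1]])[1]
    } else if (startsWith(tok, "[")) {
      substr(tok, 2, 2)
    } else tok
  }
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1
      tok <- paste(chars[i:j], collapse = "")
      i <- j + 1
    } else {
      tok <- chars[i]
      i <- i + 1
    }
    reps <- 1
    if (i <= length(chars) && chars[i] == "{") {
      j <- i
      while (chars[j] != "}") j <- j + 1
      reps <- as.integer(strsplit(paste(chars[(i + 1):(j - 1)],
                                        collapse = ""), ",")[[1]][1])
      i <- j + 1
    }
    out <- c(out, replicate(reps, emit(tok)))
  }
  paste(out, collapse = "")
}

#' Generate a synthetic peptide set with ground-truth labels
#'
#' Seed-deterministic: the same spec yields byte-identical FASTA output.
#' Ground truth is attached as `attr(set, "truth")` — a data frame with
#' columns `id` and `label` (`"inlier"` / `"outlier"`) — and is meant to be
#' written as a sidecar table, never parsed from FASTA headers, so the
#' one-class pipeline stays label-blind.
#'
#' @param spec a [synthetic_spec].
#' @return A [peptide_set] with a `truth` attribute.
#' @export
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lens_in <- sample(spec$length_range[1]:spec$length_range[2],
                      spec$n_inliers, replace = TRUE)
    inliers <- vapply(lens_in, sample_peptide, character(1),
                      composition = spec$inlier_composition)
    for (m in spec$inlier_motifs) {
      plant <- stats::runif(spec$n_inliers) < spec$plant_probability
      inliers[plant] <- vapply(inliers[plant], plant_motif_instance,
                               character(1), m = m)
    }
    lens_out <- sample(spec$length_range[1]:spec$length_range[2],
                       spec$n_outliers, replace = TRUE)
    outliers <- vapply(lens_out, sample_peptide, character(1),
                       composition = spec$outlier_composition)
    ids <- sprintf("pep_%04d", seq_len(spec$n_inliers + spec$n_outliers))
    set <- peptide_set(ids, c(inliers, outliers), source = "synthetic")
    attr(set, "truth") <- data.frame(
      id = ids,
      label = rep(c("inlier", "outlier"), c(spec$n_inliers, spec$n_outliers)),
      stringsAsFactors = FALSE)
    set
  })
}

#' Column-wise permutation of a feature matrix (synthetic negatives)
#'
#' Each column is permuted independently (its own draw from the seeded
#' stream), which preserves every per-feature marginal distribution exactly
#' while destroying the dependencies between features. The permuted rows
#' serve as synthetic negative samples. A single shared row permutation
#' would preserve the dependencies and defeat the purpose.
#'
#' @param matrix numeric matrix (>= 2 rows).
#' @param seed integer seed.
#' @param prefix row-name prefix for the synthetic negatives.
#' @export
permute_columns <- function(matrix, seed = 1, prefix = "neg_") {
  if (nrow(matrix) < 2) stop("need >= 2 samples to permute", call. = FALSE)
  out <- matrix
  with_seed(seed, {
    for (j in seq_len(ncol(matrix))) {
      out[, j] <- matrix[sample.int(nrow(matrix)), j]
    }
  })
  rownames(out) <- paste0(prefix, seq_len(nrow(matrix)))
  out
}

#' Binary-classification evaluation report
#'
#' Standard confusion-matrix metrics: per-class precision, recall and F1
#' plus overall accuracy, computed from predicted and true labels.
#' Undefined ratios (0/0) are reported as 0.
#'
#' @param predicted,truth vectors of class labels, equal length; `truth`
#'   must contain both classes.
#' @param positive the label treated as the positive class.
#' @return Object of class `evaluation_report` (a one-row data frame with
#'   confusion counts and the metric columns).
#' @export
evaluate_binary <- function(predicted, truth, positive = "pos") {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` differ in length", call. = FALSE)
  }
  classes <- unique(truth)
  if (length(classes) != 2) {
    stop("`truth` must contain exactly two classes", call. = FALSE)
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' absent from truth", call. = FALSE)
  }
  negative <- setdiff(classes, positive)
  tp <- sum(predicted == positive & truth == positive)
  fn <- sum(predicted != positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  tn <- sum(predicted != positive & truth != positive)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  prec_pos <- safe_div(tp, tp + fp)
  rec_pos <- safe_div(tp, tp + fn)
  prec_neg <- safe_div(tn, tn + fn)
  rec_neg <- safe_div(tn, tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  out <- data.frame(tp = tp, fn = fn, fp = fp, tn = tn,
                    accuracy = (tp + tn) / length(truth),
                    precision_pos = prec_pos, precision_neg = prec_neg,
                    recall_pos = rec_pos, recall_neg = rec_neg,
                    f1_pos = f1(prec_pos, rec_pos),
                    f1_neg = f1(prec_neg, rec_neg))
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Positive-vs-permuted-negative validation experiment
#'
#' Builds column-permutation synthetic negatives from the positive feature
#' matrix (1:1 ratio by default construction), standardizes and
#' PCA-reduces the combined data, and trains two binary baselines on a
#' stratified split: an RBF SVM and a supervised autoencoder (the anomaly
#' autoencoder's bottleneck encodings with a logistic classification
#' head). Returns a Table-style evaluation report per classifier, computed
#' on the held-out fraction. Seeded end to end.
#'
#' @param set a [peptide_set] of positive peptides.
#' @param config [feature_config] for featurization.
#' @param seed integer seed.
#' @param train_fraction stratified training fraction (default 0.7).
#' @param pca_variance PCA variance fraction (default 0.95).
#' @param epochs autoencoder epochs (default 50).
#' @return List with elements `svm` and `autoencoder`, each an
#'   [evaluate_binary()] report.
#' @export
run_validation_experiment <- function(set, config = feature_config(),
                                      seed = 1, train_fraction = 0.7,
                                      pca_variance = 0.95, epochs = 50) {
  x_pos <- assemble_feature_matrix(set, config)
  # split the positives first, then permute within each split: negatives
  # built from the pooled positives would smuggle test-set feature values
  # into the training negatives
  pos_train_i <- with_seed(seed + 1L, {
    sample(nrow(x_pos), round(train_fraction * nrow(x_pos)))
  })
  x_train_pos <- x_pos[pos_train_i, , drop = FALSE]
  x_test_pos <- x_pos[-pos_train_i, , drop = FALSE]
  x_train <- rbind(x_train_pos, permute_columns(x_train_pos, seed = seed))
  x_test <- rbind(x_test_pos,
                  permute_columns(x_test_pos, seed = seed + 2L))
  y_train <- rep(c("pos", "neg"), each = nrow(x_train_pos))
  y_test <- rep(c("pos", "neg"), each = nrow(x_test_pos))
  std <- fit_standardizer(x_train)
  if (all(std$constant)) {
    stop("all features are constant; positives and permuted negatives are ",
         "indistinguishable", call. = FALSE)
  }
  z_train <- apply_standardizer(std, x_train)
  z_test <- apply_standardizer(std, x_test)
  pca <- fit_pca(z_train, pca_variance)
  train_x <- pca_transform(pca, z_train)
  test_x <- pca_transform(pca, z_test)
  train_y <- factor(y_train, levels = c("neg", "pos"))
  test_y <- y_test

  svm_fit <- e1071::svm(train_x, train_y, kernel = "radial")
  svm_pred <- as.character(stats::predict(svm_fit, test_x))
  svm_report <- evaluate_binary(svm_pred, test_y, positive = "pos")

  ae <- fit_autoencoder(train_x, epochs = epochs, seed = seed + 2L)
  codes_train <- autoencoder_encode(ae, train_x)
  codes_test <- autoencoder_encode(ae, test_x)
  head_df <- data.frame(y = as.integer(train_y == "pos"), codes_train)
  head_fit <- suppressWarnings(
    stats::glm(y ~ ., data = head_df, family = stats::binomial()))
  prob <- suppressWarnings(
    stats::predict(head_fit, data.frame(codes_test), type = "response"))
  ae_pred <- ifelse(prob > 0.5, "pos", "neg")
  ae_report <- evaluate_binary(ae_pred, test_y, positive = "pos")

  list(svm = svm_report, autoencoder = ae_report)
}
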