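# Isolation forest for anomaly detection.
#
# Trees recursively split on a random feature at a random value between the
# node's min and max; points isolated after few splits are anomalies. The
# per-sample score follows the standard formulation
#   s(x) = 2 ^ ( - E[h(x)] / c(psi) )
# where h is the path length (leaves add the average-path correction c of
# their size) and psi the subsample size, so s is in (0, 1) with higher =
# more anomalous.

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# average unsuccessful-search path length in a BST of n points
avg_path_length <- function(n) {
  ifelse(n <= 1, 0,
         2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n)
}

build_itree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1 || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  rng <- apply(x, 2, range)
  usable <- which(rng[2, ] - rng[1, ] > 0)
  if (!length(usable)) return(list(leaf = TRUE, size = n))
  j <- if (length(usable) == 1) usable else sample(usable, 1)
  split <- stats::runif(1, rng[1, j], rng[2, j])
  left <- x[, j] < split
  list(leaf = FALSE, feature = j, value = split,
       left = build_itree(x[left, , drop = FALSE], depth + 1, max_depth),
       right = build_itree(x[!left, , drop = FALSE], depth + 1, max_depth))
}

# path lengths for all rows of x through one tree, vectorized over samples
itree_path <- function(node, x, idx, depth, out) {
  if (node$leaf) {
    out[idx] <- depth + avg_path_length(node$size)
    return(out)
  }
  left <- x[idx, node$feature] < node$value
  if (any(left)) out <- itree_path(node$left, x, idx[left], depth + 1, out)
  if (any(!left)) out <- itree_path(node$right, x, idx[!left], depth + 1, out)
  out
}

#' Fit an isolation forest
#'
#' @param train numeric matrix (n >= 2).
#' @param n_trees number of isolation trees (default 100).
#' @param sample_size subsample size per tree (default `min(256, n)`).
#' @param seed integer seed; same seed + data give identical forests.
#' @return Object of class `iforest_model`.
#' @export
fit_iforest <- function(train, n_trees = 100, sample_size = min(256L, nrow(train)),
                        seed = 1) {
  if (nrow(train) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  sample_size <- min(sample_size, nrow(train))
  max_depth <- ceiling(log2(max(2, sample_size)))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      rows <- sample.int(nrow(train), sample_size)
      build_itree(train[rows, , drop = FALSE], 0L, max_depth)
    })
  })
  structure(list(trees = trees, sample_size = sample_size,
                 n_trees = n_trees, p = ncol(train), seed = seed),
            class = c("iforest_model", "anomaly_model"))
}

#' @export
anomaly_scores.iforest_model <- function(model, matrix) {
  if (ncol(matrix) != model$p) stop("feature dimension mismatch", call. = FALSE)
  n <- nrow(matrix)
  total <- numeric(n)
  for (tree in model$trees) {
    total <- total + itree_path(tree, matrix, seq_len(n), 0, numeric(n))
  }
  mean_path <- total / model$n_trees
  s <- 2^(-mean_path / avg_path_length(model$sample_size))
  stats::setNames(s, rownames(matrix))
}
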