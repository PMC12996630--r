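# a transparent scorer for attribution tests: anomaly score = first column
setup_linear_scorer <- function() {
  structure(list(), class = c("first_col_model", "anomaly_model"))
}
registerS3method("anomaly_scores", "first_col_model",
                 function(model, matrix) {
                   stats::setNames(matrix[, 1], rownames(matrix))
                 },
                 envir = asNamespace("dpas"))

test_that("permutation attribution is zero for ignored features and seeded", {
  set.seed(1)
  x <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  rownames(x) <- paste0("s", 1:40)
  model <- setup_linear_scorer()

  imp <- feature_importance(model, x, n_perm = 4, seed = 2)
  expect_equal(unname(imp$global_importance[c("b", "c")]), c(0, 0))
  expect_gt(imp$global_importance["a"], 0)

  imp2 <- feature_importance(model, x, n_perm = 4, seed = 2)
  expect_identical(imp2$attributions, imp$attributions)
  expect_error(feature_importance(model, x, n_perm = 0), "n_perm")
})

test_that("duplicated feature columns receive comparable importance", {
  cloud <- make_cloud(n_in = 50, n_out = 3, p = 4, shift = 6, seed = 3)
  x <- cbind(cloud$x, dup = cloud$x[, 1])
  m <- fit_pca(apply_standardizer(fit_standardizer(x), x), 2)
  z <- apply_standardizer(fit_standardizer(x), x)
  imp <- feature_importance(m, z, n_perm = 10, seed = 4)
  g <- imp$global_importance
  ratio <- g[["f1"]] / g[["dup"]]
  expect_true(ratio > 0.5 && ratio < 2)
})

test_that("top-k selection orders by importance with name tie-break", {
  g <- c(a = 3, b = 1, c = 2)
  expect_equal(top_k_features(g, 2), c("a", "c"))
  expect_equal(top_k_features(g, 3), c("a", "c", "b"))
  expect_equal(top_k_features(c(b = 1, a = 1), 1), "a")
  expect_error(top_k_features(g, 0), "k")
  expect_error(top_k_features(g, 4), "exceeds")
})

test_that("importance term is a min-max normalized mean over chosen features", {
  attr_mat <- cbind(f1 = c(1, 2, 3), f2 = c(0, 0, 0))
  rownames(attr_mat) <- c("a", "b", "c")
  expect_equal(unname(importance_term(attr_mat, "f1")), c(0, 0.5, 1))
  expect_equal(unname(importance_term(attr_mat, "f2")), c(0, 0, 0))
  # invariant to positive rescaling
  expect_equal(importance_term(attr_mat * 37, "f1"),
               importance_term(attr_mat, "f1"))
  expect_error(importance_term(attr_mat, character(0)), "empty")
  expect_error(importance_term(attr_mat, "zz"), "unknown")
})

test_that("DPAS is the exact weighted sum with dense, deterministic ranks", {
  r <- dpas_score(c(p1 = 0.4), c(p1 = 0.6), dpas_weights(0.5, 0.5))
  expect_equal(r$dpas, 0.5)

  err <- c(a = 0.9, b = 0.1, c = 0.5)
  imp <- c(a = 0.2, b = 0.8, c = 0.5)
  r1 <- dpas_score(err, imp, dpas_weights(1, 0))
  expect_equal(r1$sample_id, c("a", "c", "b"))
  expect_equal(r1$dpas, unname(err[r1$sample_id]))

  r2 <- dpas_score(err, imp, dpas_weights(0, 1))
  expect_equal(r2$sample_id[1], "b")

  # exactness of the equation for arbitrary weights
  w <- dpas_weights(0.3, 1.7)
  r3 <- dpas_score(err, imp, w)
  expect_equal(r3$dpas,
               0.3 * r3$normalized_error + 1.7 * r3$importance_term)

  # ties share a dense rank and break by id
  r4 <- dpas_score(c(b = 0.5, a = 0.5), c(b = 0.5, a = 0.5))
  expect_equal(r4$sample_id, c("a", "b"))
  expect_equal(r4$rank, c(1L, 1L))

  expect_error(dpas_score(c(0.1, 0.2), 0.3), "length")
  expect_error(dpas_weights(0, 0), "alpha")
})

test_that("DPAS is monotone in each term for non-negative weights", {
  set.seed(5)
  err <- runif(20); imp <- runif(20)
  names(err) <- names(imp) <- sprintf("s%02d", 1:20)
  w <- dpas_weights(0.7, 0.3)
  base <- dpas_score(err, imp, w)
  bumped <- err; bumped[3] <- bumped[3] + 0.1
  r <- dpas_score(bumped, imp, w)
  expect_gt(r$dpas[r$sample_id == "s03"], base$dpas[base$sample_id == "s03"])
  expect_equal(r$dpas[r$sample_id != "s03"][order(r$sample_id[r$sample_id != "s03"])],
               base$dpas[base$sample_id != "s03"][order(base$sample_id[base$sample_id != "s03"])])
})

test_that("top-ranked peptides export in rank order", {
  set.seed(6)
  ids <- sprintf("p%02d", 1:20)
  set <- peptide_set(ids, replicate(20, random_sequence(8)))
  err <- stats::setNames(runif(20), ids)
  imp <- stats::setNames(runif(20), ids)
  ranking <- dpas_score(err, imp)
  top <- select_top(ranking, set, n = 5)
  expect_equal(top$id, ranking$sample_id[1:5])
  full <- select_top(ranking, set, n = 20)
  expect_equal(full$id, ranking$sample_id)
  expect_error(select_top(ranking, set, n = 21), "exceeds")
})
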