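test_that("amino-acid composition matches hand counts", {
  a <- aac("AAAA")
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)

  expect_equal(unname(aac("AC")[c("A", "C", "D")]), c(0.5, 0.5, 0))

  a <- aac("QRWMEDL")
  expect_equal(unname(a[c("Q", "R", "W", "M", "E", "D", "L")]),
               rep(1 / 7, 7))
  expect_equal(sum(a[setdiff(AA_ALPHABET, c("Q","R","W","M","E","D","L"))]), 0)

  expect_error(aac(""), "non-empty")
})

test_that("grouped composition aggregates aac over an 11-group scheme", {
  g <- grouped_aac("KKKK")
  expect_length(g, 11)
  expect_equal(unname(g["KR"]), 1)
  expect_equal(sum(g), 1)

  # linearity: grouped vector equals group-wise sums of aac
  scheme <- sezerman_grouping()
  set.seed(5)
  for (i in 1:20) {
    s <- random_sequence(sample(3:25, 1))
    a <- aac(s)
    expected <- vapply(scheme$groups, function(gl) sum(a[gl]), numeric(1))
    expect_equal(grouped_aac(s, scheme), expected)
  }
})

test_that("grouping schemes must partition the alphabet", {
  expect_error(grouping_scheme("bad", list(g1 = c("A", "C"))), "partition")
  expect_error(grouping_scheme("bad", list(g1 = AA_ALPHABET, g2 = "A")),
               "partition")
})

test_that("scale means behave as length-invariant averages", {
  vol <- aa_volume_scale()
  expect_equal(scale_mean("G", vol), unname(vol$values["G"]))
  expect_equal(scale_mean("GG", vol), scale_mean("G", vol))
  expect_equal(scale_mean("WWWW", vol), unname(vol$values["W"]))

  # concatenation: length-weighted mean
  hyd <- aa_hydrophobicity_scale()
  s1 <- "ACDE"; s2 <- "KLMNPQ"
  expect_equal(scale_mean(paste0(s1, s2), hyd),
               (4 * scale_mean(s1, hyd) + 6 * scale_mean(s2, hyd)) / 10)

  expect_true(scale_mean("QRWMEDL", vol) >= min(vol$values))
  expect_true(scale_mean("QRWMEDL", vol) <= max(vol$values))
})

test_that("embedded scale tables are intact (pinned checksums)", {
  sums <- tools::md5sum(c(
    system.file("extdata", "scales", "kharakoz_volume.tsv",
                package = "dpas", mustWork = TRUE),
    system.file("extdata", "scales", "hopp_woods_hydrophobicity.tsv",
                package = "dpas", mustWork = TRUE)))
  expect_equal(unname(sums),
               c("eea61d7f59b2b0f5cf1d19809f513428",
                 "14c75e758343a786cc26b9e2442f8725"))
})

test_that("physicochemical class composition has 5 fractions", {
  p <- pcp_composition("KR")
  expect_length(p, 5)
  expect_equal(unname(p["PC"]), 1)
  expect_equal(unname(pcp_composition("DE")["NC"]), 1)
  expect_equal(sum(pcp_composition("QRWMEDL")), 1)
})

test_that("composition entropy spans [0, log2 20]", {
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy(paste(AA_ALPHABET, collapse = "")), log2(20))
  expect_equal(shannon_entropy("AC"), 1)
})

test_that("repeated-residue vector is gated at count >= 2", {
  expect_equal(unname(rri("ACDE")), rep(0, 20))
  r <- rri("AAC")
  expect_equal(unname(r["A"]), 2 / 3)
  expect_equal(sum(r[names(r) != "A"]), 0)
  expect_length(rri("QRWMEDL"), 20)
})

test_that("dipeptide composition counts adjacent pairs", {
  d <- dpc("AAA")
  expect_length(d, 400)
  expect_equal(unname(d["AA"]), 1)

  d <- dpc("ACA")
  expect_equal(unname(d[c("AC", "CA")]), c(0.5, 0.5))
  expect_equal(sum(d), 1)

  expect_error(dpc("A"), "length >= 2")
})

test_that("feature matrix has the documented block layout", {
  set <- peptide_set(c("p1", "p2", "p3"), c("ACDE", "qRWmEDL", "AASSPP"))
  x <- assemble_feature_matrix(set)
  expect_equal(dim(x), c(3, 459))  # 20+11+1+1+5+1+20+400
  expect_equal(rownames(x), set$id)
  expect_equal(colnames(x)[1:20], paste0("AAC_", AA_ALPHABET))
  expect_equal(colnames(x)[32:33], c("Volume_Measure", "Hydrophobicity_Measure"))
  expect_equal(colnames(x)[39], "SER")
  expect_true(all(is.finite(x)))

  # motif block appends MOTIF_* columns; absent block appends nothing
  block <- motif_block_from_scan(set, list(motif("m1", "[ST]-P")))
  xm <- assemble_feature_matrix(set, motif_block = block)
  expect_equal(ncol(xm), 460)
  expect_equal(unname(xm[, "MOTIF_m1"]), c(0, 0, 1))

  expect_error(assemble_feature_matrix(peptide_set("p1", "A")),
               "length >= 2.*p1")
})

test_that("featurization is chunk-invariant and permutation-equivariant", {
  set.seed(9)
  set <- peptide_set(sprintf("p%02d", 1:11),
                     replicate(11, random_sequence(sample(4:12, 1))))
  x1 <- assemble_feature_matrix(set, n_chunks = 1)
  for (k in c(2, 4, 11)) {
    expect_identical(assemble_feature_matrix(set, n_chunks = k), x1)
  }
  perm <- sample(nrow(set))
  setp <- peptide_set(set$id[perm], set$raw_sequence[perm])
  xp <- assemble_feature_matrix(setp)
  expect_identical(xp, x1[perm, , drop = FALSE])
})

test_that("composition blocks sum to one on random sequences", {
  set.seed(11)
  for (i in 1:200) {
    s <- random_sequence(sample(2:30, 1))
    expect_true(abs(sum(aac(s)) - 1) < 1e-12)
    expect_true(abs(sum(dpc(s)) - 1) < 1e-12)
    expect_true(abs(sum(grouped_aac(s)) - 1) < 1e-12)
    expect_true(abs(sum(pcp_composition(s)) - 1) < 1e-12)
  }
})

test_that("feature TSV round trip preserves the matrix", {
  set <- peptide_set(c("a", "b"), c("ACDE", "MNPQ"))
  x <- assemble_feature_matrix(set)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(x, f)
  back <- read_feature_tsv(f)
  expect_equal(back, x)
})
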