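# Sequence descriptors and feature-matrix assembly.
#
# Column-name convention (fixed order, so model artifacts are portable):
#   AAC_<letter> (20), GRP_<group> (11), Volume_Measure, Hydrophobicity_Measure,
#   PCP_<class> (5), SER, RRI_<letter> (20), DPC_<pair> (400), MOTIF_<id> (m).

seq_letters <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 amino acids in the sequence:
#' `AAC(i) = count(i) / length`. Returns a 20-vector in the fixed
#' alphabetical order, summing to 1.
#'
#' @param sequence peptide string (case-insensitive).
#' @export
aac <- function(sequence) {
  s <- seq_letters(sequence)
  counts <- table(factor(s, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(s), AA_ALPHABET)
}

#' Grouped amino-acid composition over a reduced alphabet
#'
#' Group-wise sums of [aac()]: the fraction of residues falling in each
#' group of `scheme` (11 groups under the default [sezerman_grouping()]).
#'
#' @param sequence peptide string.
#' @param scheme a [grouping_scheme].
#' @export
grouped_aac <- function(sequence, scheme = sezerman_grouping()) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  a <- aac(sequence)
  vapply(scheme$groups, function(g) sum(a[g]), numeric(1))
}

#' Mean of a numeric amino-acid scale over a sequence
#'
#' Per-residue scale values summed and divided by sequence length — the
#' single-number `Volume_Measure` / `Hydrophobicity_Measure` features.
#'
#' @param sequence peptide string.
#' @param scale an [aa_scale].
#' @export
scale_mean <- function(sequence, scale) {
  stopifnot(inherits(scale, "aa_scale"))
  mean(scale$values[seq_letters(sequence)])
}

#' Physicochemical class composition (5 fractions)
#'
#' Fraction of residues in each of the five physicochemical classes
#' (hydrophobic, hydrophilic, neutral, positively charged, negatively
#' charged under the default [pcp_classes()]).
#'
#' @param sequence peptide string.
#' @param classes a [grouping_scheme] with the class memberships.
#' @export
pcp_composition <- function(sequence, classes = pcp_classes()) {
  grouped_aac(sequence, classes)
}

#' Shannon entropy of the residue composition (bits)
#'
#' `H = -sum p_i log2 p_i` over the 20 composition fractions of the
#' sequence; 0 for a homopolymer, `log2(20)` when all 20 letters are
#' equally frequent. Reported as the `SER` feature.
#'
#' @param sequence peptide string.
#' @export
shannon_entropy <- function(sequence) {
  p <- aac(sequence)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Repetitive residue information (RRI)
#'
#' Per-letter 20-vector: the length-normalized count of each amino acid
#' that occurs at least twice in the sequence; letters occurring once or
#' not at all get 0. Captures residue repetition.
#'
#' @param sequence peptide string.
#' @export
rri <- function(sequence) {
  s <- seq_letters(sequence)
  counts <- as.numeric(table(factor(s, levels = AA_ALPHABET)))
  out <- ifelse(counts >= 2, counts / length(s), 0)
  stats::setNames(out, AA_ALPHABET)
}

#' All 400 dipeptides in fixed lexicographic order (AA, AC, ..., YY)
#' @keywords internal
dipeptide_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each adjacent residue pair, normalized by the number of
#' dipeptides (`length - 1`); a 400-vector in fixed lexicographic order
#' summing to 1.
#'
#' @param sequence peptide string of length >= 2.
#' @export
dpc <- function(sequence) {
  s <- seq_letters(sequence)
  n <- length(s)
  if (n < 2) stop("dipeptide composition needs length >= 2", call. = FALSE)
  pairs <- paste0(s[-n], s[-1])
  counts <- table(factor(pairs, levels = dipeptide_names()))
  stats::setNames(as.numeric(counts) / (n - 1), dipeptide_names())
}

#' Feature configuration
#'
#' Selects which descriptor blocks to compute and which scales/schemes to
#' use. All blocks are on by default; the full non-motif panel has
#' 20 + 11 + 1 + 1 + 5 + 1 + 20 + 400 = 458 columns.
#'
#' @param aac,grouped,volume,hydrophobicity,pcp,entropy,rri,dpc logical
#'   switches per block.
#' @param grouping [grouping_scheme] for the grouped composition.
#' @param pcp_scheme [grouping_scheme] for the physicochemical classes.
#' @param volume_scale,hydrophobicity_scale [aa_scale] objects.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(aac = TRUE, grouped = TRUE, volume = TRUE,
                           hydrophobicity = TRUE, pcp = TRUE, entropy = TRUE,
                           rri = TRUE, dpc = TRUE,
                           grouping = sezerman_grouping(),
                           pcp_scheme = pcp_classes(),
                           volume_scale = aa_volume_scale(),
                           hydrophobicity_scale = aa_hydrophobicity_scale()) {
  structure(list(aac = aac, grouped = grouped, volume = volume,
                 hydrophobicity = hydrophobicity, pcp = pcp,
                 entropy = entropy, rri = rri, dpc = dpc,
                 grouping = grouping, pcp_scheme = pcp_scheme,
                 volume_scale = volume_scale,
                 hydrophobicity_scale = hydrophobicity_scale),
            class = "feature_config")
}

featurize_one <- function(sequence, config) {
  parts <- list()
  if (config$aac) {
    v <- aac(sequence)
    parts$aac <- stats::setNames(v, paste0("AAC_", names(v)))
  }
  if (config$grouped) {
    v <- grouped_aac(sequence, config$grouping)
    parts$grp <- stats::setNames(v, paste0("GRP_", names(v)))
  }
  if (config$volume) {
    parts$vol <- c(Volume_Measure = scale_mean(sequence, config$volume_scale))
  }
  if (config$hydrophobicity) {
    parts$hyd <- c(Hydrophobicity_Measure =
                     scale_mean(sequence, config$hydrophobicity_scale))
  }
  if (config$pcp) {
    v <- pcp_composition(sequence, config$pcp_scheme)
    parts$pcp <- stats::setNames(v, paste0("PCP_", names(v)))
  }
  if (config$entropy) parts$ser <- c(SER = shannon_entropy(sequence))
  if (config$rri) {
    v <- rri(sequence)
    parts$rri <- stats::setNames(v, paste0("RRI_", names(v)))
  }
  if (config$dpc) {
    v <- dpc(sequence)
    parts$dpc <- stats::setNames(v, paste0("DPC_", names(v)))
  }
  out <- unlist(parts, use.names = TRUE)
  names(out) <- sub("^[a-z]+\\.", "", names(out))
  out
}

#' Assemble the peptide feature matrix
#'
#' One row per peptide in input order; columns follow the fixed
#' block order AAC, GRP, Volume_Measure, Hydrophobicity_Measure, PCP, SER,
#' RRI, DPC, then optional MOTIF columns. Chunked execution (`n_chunks > 1`)
#' featurizes the set piecewise and concatenates, and is bit-identical to a
#' single pass — features are purely per-sequence.
#'
#' @param set a [peptide_set].
#' @param config a [feature_config].
#' @param motif_block optional [motif_vector_block] covering every sample.
#' @param n_chunks number of chunks to process (any value >= 1 yields the
#'   same matrix).
#' @return Numeric matrix with `sample_id` rownames and feature colnames;
#'   all values finite.
#' @export
assemble_feature_matrix <- function(set, config = feature_config(),
                                    motif_block = NULL, n_chunks = 1) {
  stopifnot(inherits(set, "peptide_set"))
  if (config$dpc && any(nchar(set$sequence) < 2)) {
    bad <- set$id[nchar(set$sequence) < 2]
    stop("dipeptide composition requires length >= 2; offending record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chunks <- chunk_records(set, n_chunks)
  blocks <- lapply(chunks, function(ch) {
    if (nrow(ch) == 0) return(NULL)
    rows <- lapply(ch$sequence, featurize_one, config = config)
    m <- do.call(rbind, rows)
    rownames(m) <- ch$id
    m
  })
  mat <- do.call(rbind, Filter(Negate(is.null), blocks))
  if (is.null(mat)) {
    mat <- matrix(numeric(0), nrow = 0,
                  ncol = length(featurize_one("AC", config)),
                  dimnames = list(NULL, names(featurize_one("AC", config))))
  }
  if (!is.null(motif_block)) {
    stopifnot(inherits(motif_block, "motif_vector_block"))
    mb <- motif_block$matrix
    if (!setequal(rownames(mb), set$id)) {
      stop("motif block does not cover exactly the samples of the set",
           call. = FALSE)
    }
    mb <- mb[rownames(mat), , drop = FALSE]
    colnames(mb) <- paste0("MOTIF_", motif_block$motif_ids)
    mat <- cbind(mat, mb)
  }
  if (nrow(mat) > 0 && any(!is.finite(mat))) {
    stop("non-finite value in feature matrix", call. = FALSE)
  }
  mat
}

#' Write a feature matrix as TSV (first column `sample_id`)
#' @param matrix numeric matrix with rownames and colnames.
#' @param path output path.
#' @export
write_feature_tsv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_tsv()]
#' @param path TSV path.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
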