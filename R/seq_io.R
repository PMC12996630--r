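# Reading, validating, writing and chunking peptide sequence sets.

#' The 20 canonical amino-acid letters, alphabetically ordered
#'
#' All composition features index into this fixed order.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a peptide set
#'
#' A peptide set is a data frame with one row per peptide and columns
#' `id` (unique, non-empty), `sequence` (upper-cased, validated against the
#' 20-letter alphabet) and `raw_sequence` (the input string with case
#' preserved; lowercase letters in mutated-peptide databases typically mark
#' the mutated residue, and case is recorded but never interpreted by any
#' feature).
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of peptide sequences; case-insensitive,
#'   each of length >= 1 over the 20 canonical letters.
#' @param source free-text provenance attached as an attribute.
#' @return An object of class `peptide_set` (a data frame).
#' @examples
#' peptide_set(c("p1", "p2"), c("ACDE", "qRWmEDL"))
#' @export
peptide_set <- function(id, sequence, source = "constructed") {
  id <- as.character(id)
  raw <- as.character(sequence)
  if (length(id) != length(raw)) {
    stop("`id` and `sequence` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("peptide ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate peptide ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  up <- toupper(raw)
  validate_sequences(up, id)
  out <- data.frame(id = id, sequence = up, raw_sequence = raw,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("peptide_set", "data.frame")
  out
}

validate_sequences <- function(sequences, ids) {
  if (any(!nzchar(sequences))) {
    bad <- ids[!nzchar(sequences)]
    stop("empty sequence for record(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(sequences)) {
    letters_i <- strsplit(sequences[[i]], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(letters_i), AA_ALPHABET)
    if (length(bad)) {
      stop("invalid amino-acid character(s) ", paste(bad, collapse = ", "),
           " in record '", ids[[i]], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("peptide_set with", nrow(x), "record(s); source:",
      attr(x, "source") %||% "unknown", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read peptides from a FASTA file
#'
#' One record per FASTA entry, order preserved. Multi-line sequences are
#' tolerated; case is preserved in `raw_sequence` and upper-cased in
#' `sequence`. Sequences containing letters outside the 20-letter alphabet
#' (B, J, O, U, X, Z, ...) are rejected, or skipped with a warning when
#' `skip_invalid = TRUE`.
#'
#' @param path FASTA file path.
#' @param skip_invalid drop records failing validation (with a warning
#'   reporting how many were dropped) instead of erroring.
#' @return A [peptide_set].
#' @export
read_peptide_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(peptide_set(character(), character(), source = path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (", path, "): first line must start with '>', got: ",
         first, call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  ids <- names(recs)
  raw <- vapply(recs, function(s) as.character(s)[[1]], character(1))
  if (skip_invalid) {
    ok <- vapply(seq_along(raw), function(i) {
      !inherits(try(validate_sequences(toupper(raw[[i]]), ids[[i]]),
                    silent = TRUE), "try-error")
    }, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " record(s) skipped for invalid characters",
              call. = FALSE)
    }
    ids <- ids[ok]
    raw <- raw[ok]
  }
  peptide_set(ids, raw, source = path)
}

#' Write a peptide set to FASTA
#'
#' Writes `raw_sequence` (case preserved), one sequence line per record, so
#' that a read/write round trip reproduces ids and raw sequences exactly.
#'
#' @param set a [peptide_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(set, path) {
  stopifnot(inherits(set, "peptide_set"))
  if (anyDuplicated(set$id)) stop("duplicate ids in peptide set", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(set) > 0) {
    writeLines(paste0(">", set$id, "\n", set$raw_sequence), con, sep = "\n")
  }
  invisible(path)
}

#' Split a peptide set into balanced, ordered chunks
#'
#' Partitions the set in order into `n_chunks` pieces whose sizes differ by
#' at most one, so that large sets can be featurized chunk-wise and the
#' chunk results concatenated. When `n_chunks` exceeds the number of
#' records, the trailing chunks are empty.
#'
#' @param set a [peptide_set].
#' @param n_chunks positive integer.
#' @return List of `n_chunks` peptide sets; concatenating them restores the
#'   original order.
#' @export
chunk_records <- function(set, n_chunks) {
  stopifnot(inherits(set, "peptide_set"))
  if (!is.numeric(n_chunks) || length(n_chunks) != 1 || n_chunks < 1 ||
      n_chunks != floor(n_chunks)) {
    stop("`n_chunks` must be a positive integer", call. = FALSE)
  }
  n <- nrow(set)
  sizes <- rep(n %/% n_chunks, n_chunks)
  extra <- n %% n_chunks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_chunks), function(k) {
    if (sizes[k] == 0) {
      peptide_set(character(), character(), source = attr(set, "source"))
    } else {
      rows <- set[starts[k]:ends[k], , drop = FALSE]
      peptide_set(rows$id, rows$raw_sequence, source = attr(set, "source"))
    }
  })
}
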