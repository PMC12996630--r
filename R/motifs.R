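# Binary motif-occurrence features from PROSITE-style patterns or from an
# external (MAST-style) tabular hit file.

#' Compile a PROSITE-style motif pattern
#'
#' Supported syntax: residue letters; `x` (any residue); bracket classes
#' `[ST]`; negated classes `{P}`; repeats `x(2)` / `x(2,4)` after any
#' element; elements optionally separated by `-`; `<` / `>` anchor the
#' pattern to the sequence start / end; a trailing `.` is ignored.
#' Consensus strings without separators (e.g. `SP`) are also accepted.
#'
#' @param id motif identifier.
#' @param pattern pattern string.
#' @return An object of class `motif` carrying the compiled regular
#'   expression.
#' @export
motif <- function(id, pattern) {
  structure(list(id = as.character(id), pattern = pattern,
                 regex = prosite_to_regex(pattern)),
            class = "motif")
}

prosite_to_regex <- function(pattern) {
  p <- gsub("\\s", "", pattern)
  p <- sub("\\.$", "", p)
  anchor_start <- startsWith(p, "<")
  anchor_end <- endsWith(p, ">")
  if (anchor_start) p <- substring(p, 2)
  if (anchor_end) p <- substring(p, 1, nchar(p) - 1)
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  i <- 1L
  out <- character(0)
  fail <- function(msg) {
    stop("unparseable motif pattern '", pattern, "': ", msg, call. = FALSE)
  }
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "-") { i <- i + 1L; next }
    if (ch %in% c("x", "X")) {
      elem <- "."
      i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[[j]] != "]") j <- j + 1L
      if (j > length(chars)) fail("unclosed '['")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      if (!nzchar(inner) || !grepl("^[A-Za-z]+$", inner)) fail("bad class")
      elem <- paste0("[", toupper(inner), "]")
      i <- j + 1L
    } else if (ch == "{") {
      j <- i
      while (j <= length(chars) && chars[[j]] != "}") j <- j + 1L
      if (j > length(chars)) fail("unclosed '{'")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      if (!nzchar(inner) || !grepl("^[A-Za-z]+$", inner)) fail("bad class")
      elem <- paste0("[^", toupper(inner), "]")
      i <- j + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      elem <- toupper(ch)
      i <- i + 1L
    } else {
      fail(paste0("unexpected character '", ch, "'"))
    }
    # optional repeat count (n) or (n,m)
    if (i <= length(chars) && chars[[i]] == "(") {
      j <- i
      while (j <= length(chars) && chars[[j]] != ")") j <- j + 1L
      if (j > length(chars)) fail("unclosed '('")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", inner)) fail("bad repeat count")
      elem <- paste0(elem, "{", inner, "}")
      i <- j + 1L
    }
    out <- c(out, elem)
  }
  if (!length(out)) fail("empty pattern")
  paste0(if (anchor_start) "^", paste(out, collapse = ""),
         if (anchor_end) "$")
}

#' Parse a motif definition file
#'
#' One motif per line, `id<TAB>pattern`; blank lines and `#` comments are
#' skipped. Every pattern is compiled on read, so errors name the offending
#' line.
#'
#' @param path file path.
#' @return List of [motif] objects with unique ids.
#' @export
parse_motifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  motifs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("line ", k, " is not 'id<TAB>pattern': ", lines[[k]], call. = FALSE)
    }
    m <- tryCatch(motif(parts[[1]], parts[[2]]), error = function(e) {
      stop("line ", k, ": ", conditionMessage(e), call. = FALSE)
    })
    motifs[[k]] <- m
    ids[[k]] <- m$id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate motif ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  motifs
}

#' Does a motif match anywhere in a sequence?
#'
#' Case-insensitive: the sequence is upper-cased before matching.
#'
#' @param sequence peptide string.
#' @param motif a [motif].
#' @return `TRUE` iff the pattern matches at any position.
#' @export
scan_sequence <- function(sequence, motif) {
  stopifnot(inherits(motif, "motif"))
  grepl(motif$regex, toupper(sequence), perl = TRUE)
}

new_motif_block <- function(motif_ids, matrix) {
  stopifnot(all(matrix %in% c(0, 1)))
  structure(list(motif_ids = motif_ids, matrix = matrix),
            class = "motif_vector_block")
}

#' Binary motif-occurrence block by direct pattern scan
#'
#' Entry (i, j) is 1 iff motif j matches peptide i; column order follows
#' the motif input order.
#'
#' @param set a [peptide_set].
#' @param motifs list of [motif] objects.
#' @return A `motif_vector_block` with a binary samples x motifs matrix.
#' @export
motif_block_from_scan <- function(set, motifs) {
  stopifnot(inherits(set, "peptide_set"))
  ids <- vapply(motifs, function(m) m$id, character(1))
  mat <- matrix(0, nrow = nrow(set), ncol = length(motifs),
                dimnames = list(set$id, ids))
  for (j in seq_along(motifs)) {
    mat[, j] <- as.numeric(vapply(set$sequence, scan_sequence,
                                  logical(1), motif = motifs[[j]]))
  }
  new_motif_block(ids, mat)
}

#' Binary motif-occurrence block from an external hit table
#'
#' Consumes a MAST-style table of `(sample_id, motif_id, evalue)` rows.
#' Under the default significance convention (`evalue_direction = "le"`) an
#' entry is 1 iff some hit for that pair has E-value at or below the
#' threshold; `"ge"` inverts the comparison. Duplicated pairs keep their
#' best (minimum) E-value. Samples or motifs with no hits stay 0.
#'
#' @param set a [peptide_set].
#' @param motif_ids ordered character vector of motif column ids.
#' @param hits data frame with columns `sample_id`, `motif_id`, `evalue`
#'   (all E-values > 0).
#' @param evalue_threshold positive threshold.
#' @param evalue_direction `"le"` (significant = small E-value, default) or
#'   `"ge"`.
#' @export
motif_block_from_hits <- function(set, motif_ids, hits, evalue_threshold,
                                  evalue_direction = c("le", "ge")) {
  stopifnot(inherits(set, "peptide_set"), evalue_threshold > 0)
  evalue_direction <- match.arg(evalue_direction)
  if (nrow(hits) > 0) {
    stopifnot(all(c("sample_id", "motif_id", "evalue") %in% names(hits)))
    if (any(hits$evalue <= 0)) stop("E-values must be > 0", call. = FALSE)
    bad_s <- setdiff(unique(hits$sample_id), set$id)
    bad_m <- setdiff(unique(hits$motif_id), motif_ids)
    if (length(bad_s) || length(bad_m)) {
      stop("hits reference unknown ",
           if (length(bad_s)) paste0("sample(s) ", paste(bad_s, collapse = ", ")),
           if (length(bad_s) && length(bad_m)) "; ",
           if (length(bad_m)) paste0("motif(s) ", paste(bad_m, collapse = ", ")),
           call. = FALSE)
    }
  }
  mat <- matrix(0, nrow = nrow(set), ncol = length(motif_ids),
                dimnames = list(set$id, motif_ids))
  if (nrow(hits) > 0) {
    best <- stats::aggregate(evalue ~ sample_id + motif_id, data = hits,
                             FUN = min)
    keep <- if (evalue_direction == "le") {
      best$evalue <= evalue_threshold
    } else {
      best$evalue >= evalue_threshold
    }
    best <- best[keep, , drop = FALSE]
    if (nrow(best) > 0) {
      mat[cbind(best$sample_id, best$motif_id)] <- 1
    }
  }
  new_motif_block(motif_ids, mat)
}

#' Read a MAST-style hit table (`sample_id<TAB>motif_id<TAB>evalue`)
#' @param path TSV path with a header row.
#' @export
read_motif_hits <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"),
                    stringsAsFactors = FALSE)
}
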