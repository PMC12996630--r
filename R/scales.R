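# Amino-acid numeric scales and alphabet groupings.
#
# Scale constants are shipped as commented TSV files under
# inst/extdata/scales/ so they are versioned, citable and swappable.

#' Construct an amino-acid scale
#'
#' A named mapping from each of the 20 canonical letters to a real number.
#'
#' @param name scale name.
#' @param values named numeric vector with exactly the 20 letters as names.
#' @return An object of class `aa_scale`.
#' @export
aa_scale <- function(name, values) {
  if (!setequal(names(values), AA_ALPHABET) || length(values) != 20) {
    stop("scale '", name, "' must map exactly the 20 amino-acid letters",
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("scale values must be finite", call. = FALSE)
  structure(list(name = name, values = values[AA_ALPHABET]),
            class = "aa_scale")
}

#' Read an amino-acid scale from a two-column TSV
#'
#' Lines starting with `#` are comments; the remaining lines are
#' `letter<TAB>value`, one per amino acid, all 20 required.
#'
#' @param path TSV file path.
#' @param name scale name; defaults to the file stem.
#' @export
read_aa_scale <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("letter", "value"),
                           colClasses = c("character", "numeric"))
  aa_scale(name, stats::setNames(tab$value, tab$letter))
}

scale_file <- function(fname) {
  system.file("extdata", "scales", fname, package = "dpas", mustWork = TRUE)
}

#' Built-in residue volume scale (Kharakoz estimates)
#'
#' Residue volumes in cubic Angstrom; the sequence mean is the
#' `Volume_Measure` feature.
#' @export
aa_volume_scale <- function() read_aa_scale(scale_file("kharakoz_volume.tsv"),
                                            name = "kharakoz_volume")

#' Built-in Hopp-Woods hydrophilicity scale
#'
#' The sequence mean is the `Hydrophobicity_Measure` feature.
#' @export
aa_hydrophobicity_scale <- function() {
  read_aa_scale(scale_file("hopp_woods_hydrophobicity.tsv"),
                name = "hopp_woods_hydrophobicity")
}

#' Construct a grouping scheme
#'
#' An ordered partition of the 20-letter alphabet into named groups, used
#' for reduced-alphabet composition features.
#'
#' @param name scheme name.
#' @param groups named list of character vectors; the vectors must be
#'   disjoint and jointly cover all 20 letters.
#' @return An object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(name, groups) {
  letters_all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(letters_all) || !setequal(letters_all, AA_ALPHABET)) {
    stop("groups of scheme '", name,
         "' must partition the 20-letter alphabet", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("every group needs a label", call. = FALSE)
  }
  structure(list(name = name, groups = groups), class = "grouping_scheme")
}

#' Read a grouping scheme from a two-column TSV (`label<TAB>letters`)
#'
#' @param path TSV file path; lines starting with `#` are comments.
#' @param name scheme name; defaults to the file stem.
#' @export
read_grouping_scheme <- function(path,
                                 name = tools::file_path_sans_ext(basename(path))) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("label", "letters"),
                           colClasses = "character")
  groups <- lapply(tab$letters, function(s) strsplit(toupper(s), "")[[1]])
  names(groups) <- tab$label
  grouping_scheme(name, groups)
}

#' Default 11-group reduced alphabet (Sezerman-style grouping)
#'
#' Partitions the 20 letters into 11 physicochemically coherent groups
#' (aliphatic IVLM; aromatic FWY; hydroxyl ST; amide NQ; acidic DE; basic
#' KR; and the singletons A, G, C, P, H), giving an 11-dimensional grouped
#' composition vector. The membership is a documented default and can be
#' replaced by any user-supplied 11-group scheme via
#' [read_grouping_scheme()].
#' @export
sezerman_grouping <- function() {
  grouping_scheme("sezerman11", list(
    IVLM = c("I", "V", "L", "M"),
    FWY  = c("F", "W", "Y"),
    ST   = c("S", "T"),
    NQ   = c("N", "Q"),
    DE   = c("D", "E"),
    KR   = c("K", "R"),
    A    = "A",
    G    = "G",
    C    = "C",
    P    = "P",
    H    = "H"
  ))
}

#' Default 5-class physicochemical partition
#'
#' Classes: hydrophobic (HB: A,C,F,I,L,M,V,W), hydrophilic (HL: N,Q,S,T,Y),
#' neutral (NT: G,P), positively charged (PC: K,R,H) and negatively charged
#' (NC: D,E). The membership is a documented default, overridable via
#' [read_grouping_scheme()].
#' @export
pcp_classes <- function() {
  grouping_scheme("pcp5", list(
    HB = c("A", "C", "F", "I", "L", "M", "V", "W"),
    HL = c("N", "Q", "S", "T", "Y"),
    NT = c("G", "P"),
    PC = c("K", "R", "H"),
    NC = c("D", "E")
  ))
}
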