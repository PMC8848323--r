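#' Construct a genome assembly object
#'
#' An assembly is an ordered set of uniquely named nucleotide sequences over
#' the alphabet {A,C,G,T,N}, stored uppercase as a [Biostrings::DNAStringSet].
#' All internal coordinates in synpaint are 0-based half-open; conversions to
#' the 1-based conventions of GFF3, RepeatMasker and BLAST tabular output
#' happen only at the I/O boundary.
#'
#' @param seq named character vector or named `DNAStringSet` of sequences.
#' @param name label for the assembly.
#' @param permissive if `TRUE`, IUPAC ambiguity codes are mapped to `N`
#'   (with the substitution count recorded in the `n_mapped` attribute);
#'   if `FALSE` (default) any letter outside {A,C,G,T,N} is an error.
#' @return an object of class `"assembly"`: a list with elements `seq`
#'   (a `DNAStringSet`) and `name`.
#' @examples
#' a <- assembly(c(chr1 = "ACGTACGT", chr2 = "NNNAC"), name = "toy")
#' seq_lengths(a)
#' @export
assembly <- function(seq, name = "assembly", permissive = FALSE) {
  if (is.character(seq)) {
    if (is.null(names(seq)) || anyNA(names(seq)) || any(names(seq) == ""))
      stop("all sequences must be named")
    # DNAStringSet uppercases on construction and rejects non-IUPAC letters
    dss <- tryCatch(Biostrings::DNAStringSet(seq),
                    error = function(e)
                      stop("illegal characters in sequence: ",
                           conditionMessage(e)))
  } else if (methods::is(seq, "DNAStringSet")) {
    dss <- seq
  } else {
    stop("seq must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(dss)))
    stop("duplicate sequence ids: ",
         paste(unique(names(dss)[duplicated(names(dss))]), collapse = ", "))
  nmapped <- 0L
  af <- colSums(Biostrings::alphabetFrequency(dss))
  extra <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
  extra <- extra[extra > 0]
  if (length(extra)) {
    gapish <- intersect(names(extra), c("-", "+", "."))
    if (length(gapish))
      stop("illegal characters in sequence: ",
           paste(gapish, collapse = ""))
    if (!permissive)
      stop("illegal characters in sequence: ",
           paste(names(extra), collapse = ""),
           " (set permissive = TRUE to map IUPAC ambiguity codes to N)")
    nmapped <- sum(extra)
    dss <- Biostrings::chartr("RYSWKMBDHV", strrep("N", 10), dss)
    message(nmapped, " IUPAC ambiguity bases mapped to N")
  }
  obj <- structure(list(seq = dss, name = name), class = "assembly")
  attr(obj, "n_mapped") <- nmapped
  obj
}

#' @export
print.assembly <- function(x, ...) {
  w <- Biostrings::width(x$seq)
  cat(sprintf("<assembly> %s: %d sequences, %s bp total\n",
              x$name, length(x$seq), format(sum(as.numeric(w)), big.mark = ",")))
  n <- min(length(x$seq), 8L)
  for (i in seq_len(n))
    cat(sprintf("  %s  %s bp\n", names(x$seq)[i], format(w[i], big.mark = ",")))
  if (length(x$seq) > n) cat("  ...\n")
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param x an `assembly`.
#' @return named integer vector of sequence lengths in bp.
#' @export
seq_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  stats::setNames(Biostrings::width(x$seq), names(x$seq))
}

#' Total assembly length in bp
#' @param x an `assembly`.
#' @export
total_length <- function(x) sum(as.numeric(seq_lengths(x)))
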