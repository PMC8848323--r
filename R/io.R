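# File readers and writers. Internal convention: 0-based half-open intervals
# everywhere; 1-based external formats (GFF3, RepeatMasker .out, BLAST
# tabular sstart) are converted here and only here.

#' Read a FASTA file into an assembly
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. Plain and gzip-compressed files are accepted.
#'
#' @param path FASTA file.
#' @param name assembly label (defaults to the file name).
#' @param permissive map IUPAC ambiguity codes to `N` instead of erroring.
#' @return an [assembly].
#' @export
read_fasta <- function(path, name = basename(path), permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("failed to parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- as.character(dss)
  names(chr) <- ids
  assembly(chr, name = name, permissive = permissive)
}

#' Write an assembly to FASTA
#'
#' @param x an [assembly].
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "assembly"))
  Biostrings::writeXStringSet(x$seq, path, width = width)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' GFF3 coordinates are 1-based inclusive; returned intervals are 0-based
#' half-open. Comment and directive lines are skipped.
#'
#' @param path GFF3 file.
#' @param feature_type value of column 3 to keep (default `"gene"`).
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `kind`, `attrs`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(feature_frame(character(0), integer(0), integer(0),
                         character(0), "gene", character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 9))
    stop("malformed GFF3 row at line ", lineno[which(ncol < 9)[1]],
         ": expected 9 tab-separated columns")
  m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9, byrow = TRUE)
  sel <- m[, 3] == feature_type
  m <- m[sel, , drop = FALSE]
  ln <- lineno[sel]
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(start1) || anyNA(end1))
    stop("non-numeric coordinate at line ", ln[which(is.na(start1) | is.na(end1))[1]])
  bad <- start1 > end1
  if (any(bad))
    stop("start > end at line ", ln[which(bad)[1]])
  feature_frame(m[, 1], start1 - 1, end1, m[, 7], feature_type, m[, 9])
}

feature_frame <- function(seq_id, start, end, strand, kind, attrs) {
  data.frame(seq_id = as.character(seq_id), start = as.numeric(start),
             end = as.numeric(end),
             strand = if (length(strand)) as.character(strand) else character(0),
             kind = rep_len(kind, length(seq_id)),
             attrs = as.character(attrs), stringsAsFactors = FALSE)
}

#' Read repeat intervals from BED or RepeatMasker .out
#'
#' BED input is 0-based half-open and used as is; RepeatMasker `.out` is
#' 1-based inclusive with three header lines and is converted. The repeat
#' family (BED name column or RepeatMasker repeat/class fields) is stored in
#' `attrs`.
#'
#' @param path input file.
#' @param format `"bed"` or `"repeatmasker_out"`.
#' @return data.frame of intervals with `kind = "repeat"` (see
#'   [read_gff3_genes] for columns).
#' @export
read_repeat_intervals <- function(path, format = c("bed", "repeatmasker_out")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lineno <- which(keep); lines <- lines[keep]
    if (!length(lines))
      return(feature_frame(character(0), integer(0), integer(0),
                           character(0), "repeat", character(0)))
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 3))
      stop("malformed BED row at line ", lineno[which(lengths(f) < 3)[1]])
    chrom <- vapply(f, `[`, "", 1)
    s <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
    e <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
    if (anyNA(s) || anyNA(e))
      stop("non-numeric BED coordinate at line ", lineno[which(is.na(s) | is.na(e))[1]])
    fam <- vapply(f, function(z) if (length(z) >= 4) z[4] else ".", "")
    strand <- vapply(f, function(z) if (length(z) >= 6) z[6] else ".", "")
    feature_frame(chrom, s, e, strand, "repeat", fam)
  } else {
    lines <- readLines(path)
    if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
    keep <- nzchar(trimws(lines))
    lineno <- which(keep) + 3L; lines <- lines[keep]
    if (!length(lines))
      return(feature_frame(character(0), integer(0), integer(0),
                           character(0), "repeat", character(0)))
    f <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(f) < 11))
      stop("malformed RepeatMasker row at line ", lineno[which(lengths(f) < 11)[1]])
    chrom <- vapply(f, `[`, "", 5)
    s <- suppressWarnings(as.numeric(vapply(f, `[`, "", 6)))
    e <- suppressWarnings(as.numeric(vapply(f, `[`, "", 7)))
    if (anyNA(s) || anyNA(e))
      stop("non-numeric RepeatMasker coordinate at line ",
           lineno[which(is.na(s) | is.na(e))[1]])
    strand <- vapply(f, `[`, "", 9)
    strand[strand == "C"] <- "-"
    fam <- paste(vapply(f, `[`, "", 10), vapply(f, `[`, "", 11), sep = "/")
    feature_frame(chrom, s - 1, e, strand, "repeat", fam)
  }
}

#' Read a BLAST tabular hit table
#'
#' Default dialect is the 5-column custom format
#' `qseqid sseqid sstart length pident` (tab-separated, no header);
#' `columns` names the columns of the file in order and may describe any
#' dialect containing those five fields, e.g. the standard 12-column
#' `outfmt 6` via [blast12_columns()]. `sstart` is kept 1-based as printed;
#' downstream marker processing converts it.
#'
#' @param path hit table (plain or gzip).
#' @param columns character vector naming every file column.
#' @return data.frame with columns `qseqid`, `sseqid`, `sstart`, `length`,
#'   `pident`, rows in file order.
#' @export
read_hit_table <- function(path,
                           columns = c("qseqid", "sseqid", "sstart",
                                       "length", "pident")) {
  if (!file.exists(path)) stop("file not found: ", path)
  req <- c("qseqid", "sseqid", "sstart", "length", "pident")
  if (!all(req %in% columns))
    stop("columns must include: ", paste(req, collapse = ", "))
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L)
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      sstart = numeric(0), length = numeric(0),
                      pident = numeric(0), stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) != length(columns))
    stop("hit table has ", ncol(df), " columns, expected ", length(columns))
  names(df) <- columns
  out <- df[, req]
  for (col in c("sstart", "length", "pident")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " at row ", which(is.na(v))[1])
    out[[col]] <- v
  }
  if (any(out$length < 1)) stop("alignment length < 1 at row ",
                                which(out$length < 1)[1])
  if (any(out$pident < 0 | out$pident > 100))
    stop("pident outside [0,100] at row ",
         which(out$pident < 0 | out$pident > 100)[1])
  out
}

#' Column order of standard 12-column BLAST outfmt 6
#' @export
blast12_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

#' Write syntenic blocks as BED6
#'
#' Query coordinates, 0-based half-open. The name field is
#' `<species>:<target_scaffold>`; the BED score is the block marker count
#' capped at 1000 (true counts live in the TSV written by
#' [write_painting_tsv]).
#'
#' @param painting a `painting` object or its `blocks` data.frame.
#' @param path output file.
#' @export
write_painting_bed <- function(painting, path) {
  b <- if (inherits(painting, "painting")) painting$blocks else painting
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synpaint painting; coordinates 0-based half-open (query)", con)
  if (nrow(b)) {
    bed <- data.frame(chrom = b$query_chrom, start = b$query_start,
                      end = b$query_end,
                      name = paste0(b$species, ":", b$target_scaffold),
                      score = pmin(b$marker_count, 1000L), strand = ".")
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write syntenic blocks as an annotated TSV
#'
#' @param painting a `painting` object or its `blocks` data.frame.
#' @param path output file.
#' @export
write_painting_tsv <- function(painting, path) {
  b <- if (inherits(painting, "painting")) painting$blocks else painting
  cols <- c("species", "query_chrom", "first_index", "last_index",
            "marker_count", "target_scaffold", "target_min", "target_max",
            "query_start", "query_end")
  meta <- "painting blocks; coordinates 0-based half-open"
  if (inherits(painting, "painting"))
    meta <- c(meta, sprintf("params: marker_len=%d min_aln_len=%d min_run=%d drop_n=%s",
                            painting$params$marker_len, painting$params$min_aln_len,
                            painting$params$min_run, painting$params$drop_n))
  write_tsv_with_header(b[, intersect(cols, names(b))], path, meta)
}

#' Read a painting TSV written by [write_painting_tsv]
#' @param path file.
#' @return data.frame of blocks.
#' @export
read_painting_tsv <- function(path) read_tsv_skip_comments(path)
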