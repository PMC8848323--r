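# In silico chromosome painting: fixed-length marker partition of the query
# genome, best-hit filtering, and chaining of consecutive markers into
# syntenic blocks.

#' Partition an assembly into fixed-length markers
#'
#' The query genome is tiled from position 0 into non-overlapping windows of
#' exactly `marker_len` bp; the trailing partial tile is dropped. Tiles
#' containing one or more `N` bases are dropped when `drop_n = TRUE`
#' (the default), otherwise kept with `contains_n` flagged.
#'
#' Two numberings are carried: `tile` is the 0-based ordinal of the tile
#' counting *all* tiles (dropped ones included) — it defines the marker id
#' `<chrom>_<zero-padded tile>` and the consecutiveness used in chaining, so
#' a dropped gap tile breaks a run; `index` is the 0-based rank among kept
#' markers on the chromosome.
#'
#' @param x an [assembly].
#' @param marker_len marker length in bp (default 100, minimum 10).
#' @param drop_n drop tiles containing any `N`.
#' @return data.frame with columns `marker_id`, `query_chrom`, `tile`,
#'   `index`, `start`, `end`, `contains_n`.
#' @export
generate_markers <- function(x, marker_len = 100L, drop_n = TRUE) {
  stopifnot(inherits(x, "assembly"))
  if (marker_len < 10) stop("marker_len must be >= 10")
  marker_len <- as.integer(marker_len)
  pieces <- vector("list", length(x$seq))
  for (i in seq_along(x$seq)) {
    chrom <- names(x$seq)[i]
    L <- Biostrings::width(x$seq)[i]
    n_tiles <- L %/% marker_len
    if (n_tiles == 0L) next
    starts <- (seq_len(n_tiles) - 1L) * marker_len
    v <- Biostrings::Views(x$seq[[i]], start = starts + 1L, width = marker_len)
    ncount <- Biostrings::letterFrequency(v, "N")[, 1]
    contains_n <- ncount > 0L
    keep <- if (drop_n) !contains_n else rep(TRUE, n_tiles)
    if (!any(keep)) next
    tile <- (seq_len(n_tiles) - 1L)[keep]
    pieces[[i]] <- data.frame(
      query_chrom = chrom, tile = tile,
      start = starts[keep], end = starts[keep] + marker_len,
      contains_n = contains_n[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(query_chrom = character(0), tile = integer(0),
                      start = numeric(0), end = numeric(0),
                      contains_n = logical(0), stringsAsFactors = FALSE)
  pad <- max(6L, nchar(max(c(0L, out$tile))))
  out$marker_id <- sprintf(paste0("%s_%0", pad, "d"), out$query_chrom, out$tile)
  out$index <- stats::ave(out$tile, out$query_chrom,
                          FUN = function(z) seq_along(z) - 1L)
  attr(out, "marker_len") <- marker_len
  out[, c("marker_id", "query_chrom", "tile", "index", "start", "end",
          "contains_n")]
}

#' Parse marker ids back to (chromosome, tile ordinal)
#'
#' Marker ids are `<chrom>_<zero-padded tile>`; the trailing digit group
#' after the last underscore is the tile, everything before it the
#' chromosome (chromosome names may themselves contain underscores).
#'
#' @param ids character vector of marker ids.
#' @return data.frame with columns `query_chrom`, `tile`.
#' @export
parse_marker_id <- function(ids) {
  ok <- grepl("^.+_[0-9]+$", ids)
  if (!all(ok)) stop("unparseable marker id: ", ids[which(!ok)[1]])
  data.frame(query_chrom = sub("_[0-9]+$", "", ids),
             tile = as.integer(sub("^.*_", "", ids)),
             stringsAsFactors = FALSE)
}

#' Reduce a raw hit table to at most one hit per marker
#'
#' Replicates `-max_hsps 1 -max_target_seqs 1` behaviour in software for
#' dialects that do not guarantee it. Ties are broken deterministically by
#' (max alignment length, max percent identity, lexicographic target
#' scaffold, min target start), so the result is invariant to row order.
#' Hits whose `qseqid` does not match a generated marker are dropped and
#' counted in the `n_unknown` attribute. Target starts are converted from
#' the 1-based tabular convention to 0-based.
#'
#' @param hits data.frame from [read_hit_table].
#' @param markers data.frame from [generate_markers].
#' @param species target species label attached to the retained hits.
#' @return data.frame of retained hits: `marker_id`, `query_chrom`, `tile`,
#'   `species`, `target_scaffold`, `target_start`, `aln_length`, `pident`.
#' @export
select_best_hits <- function(hits, markers, species) {
  known <- hits$qseqid %in% markers$marker_id
  n_unknown <- sum(!known)
  h <- hits[known, , drop = FALSE]
  if (nrow(h)) {
    o <- order(h$qseqid, -h$length, -h$pident, h$sseqid, h$sstart)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$qseqid), , drop = FALSE]
  }
  mi <- match(h$qseqid, markers$marker_id)
  out <- data.frame(
    marker_id = h$qseqid,
    query_chrom = markers$query_chrom[mi],
    tile = markers$tile[mi],
    species = rep_len(species, nrow(h)),
    target_scaffold = h$sseqid,
    target_start = h$sstart - 1,
    aln_length = h$length,
    pident = h$pident,
    stringsAsFactors = FALSE)
  out <- out[order(out$query_chrom, out$tile), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Filter retained hits by minimum alignment length
#'
#' The painting homology condition keeps a marker only if its alignment
#' covers at least `min_aln_len` bp (default 50 of the 100-bp marker).
#'
#' @param retained data.frame from [select_best_hits].
#' @param min_aln_len minimum alignment length in bp.
#' @return the retained hits with `aln_length >= min_aln_len`, order kept.
#' @export
filter_hits <- function(retained, min_aln_len = 50L) {
  out <- retained[retained$aln_length >= min_aln_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain consecutive retained markers into syntenic blocks
#'
#' Within each query chromosome, maximal runs of markers whose tile
#' ordinals differ by exactly 1 and whose best hits share one target
#' scaffold form candidate blocks; runs of at least `min_run` markers
#' (default 5) are emitted. Target-side collinearity is not required by
#' default; `require_collinear = TRUE` additionally breaks a run where
#' `target_start` stops being strictly monotone in the run's direction.
#'
#' @param filtered retained hits for a single species
#'   (from [filter_hits]).
#' @param min_run minimum markers per block.
#' @param require_collinear strict mode; see Details.
#' @param marker_len marker length used for query spans (default taken from
#'   100 bp if not recoverable).
#' @return data.frame of blocks: `species`, `query_chrom`, `first_index`,
#'   `last_index` (tile ordinals, inclusive), `marker_count`,
#'   `target_scaffold`, `target_min`, `target_max`, `query_start`,
#'   `query_end`.
#' @export
chain_markers <- function(filtered, min_run = 5L, require_collinear = FALSE,
                          marker_len = 100L) {
  empty <- data.frame(species = character(0), query_chrom = character(0),
                      first_index = integer(0), last_index = integer(0),
                      marker_count = integer(0), target_scaffold = character(0),
                      target_min = numeric(0), target_max = numeric(0),
                      query_start = numeric(0), query_end = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(filtered) == 0L) return(empty)
  if (length(unique(filtered$species)) > 1L)
    stop("chain_markers expects hits for a single species")
  key <- paste(filtered$query_chrom, filtered$tile, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (marker, species) hits: select_best_hits violated")
  h <- filtered[order(filtered$query_chrom, filtered$tile), , drop = FALSE]
  n <- nrow(h)
  brk <- c(TRUE,
           h$query_chrom[-1] != h$query_chrom[-n] |
           h$tile[-1] - h$tile[-n] != 1L |
           h$target_scaffold[-1] != h$target_scaffold[-n])
  if (require_collinear && n >= 2L) {
    step <- c(NA, diff(h$target_start))
    # direction established by the first step of a run; a sign change or a
    # zero step starts a new run
    run0 <- cumsum(brk)
    dirbrk <- rep(FALSE, n)
    dir <- 0
    for (i in 2:n) {
      if (brk[i]) { dir <- 0; next }
      s <- sign(step[i])
      if (s == 0) { dirbrk[i] <- TRUE; dir <- 0; next }
      if (dir == 0) dir <- s
      else if (s != dir) { dirbrk[i] <- TRUE; dir <- s }
    }
    brk <- brk | dirbrk
  }
  run <- cumsum(brk)
  agg <- function(v, f) as.vector(tapply(v, run, f))
  blocks <- data.frame(
    species = agg(h$species, function(z) z[1]),
    query_chrom = agg(h$query_chrom, function(z) z[1]),
    first_index = agg(h$tile, min),
    last_index = agg(h$tile, max),
    marker_count = agg(h$tile, length),
    target_scaffold = agg(h$target_scaffold, function(z) z[1]),
    target_min = agg(h$target_start, min),
    target_max = agg(h$target_start + h$aln_length, max),
    stringsAsFactors = FALSE)
  blocks$query_start <- blocks$first_index * marker_len
  blocks$query_end <- (blocks$last_index + 1) * marker_len
  blocks <- blocks[blocks$marker_count >= min_run, , drop = FALSE]
  blocks <- blocks[order(blocks$query_chrom, blocks$first_index), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' In silico chromosome painting of a query genome
#'
#' Runs the full painting pipeline — marker partition, per-species best-hit
#' selection, alignment-length filtering, and chaining into syntenic blocks
#' — for every target species hit table.
#'
#' @param x query [assembly].
#' @param hit_tables named list (species -> hit table data.frame as read by
#'   [read_hit_table]).
#' @param marker_len marker length (bp).
#' @param min_aln_len minimum retained alignment length (bp).
#' @param min_run minimum consecutive markers per syntenic block.
#' @param drop_n drop marker tiles containing `N`.
#' @param require_collinear strict target-collinearity mode
#'   (see [chain_markers]).
#' @return object of class `"painting"`: list with `blocks` (one data.frame
#'   across species, sorted by species, chromosome, first index), `stats`
#'   (per-species marker/hit/block retention counts), `markers`, `params`,
#'   `species`, `assembly_name`.
#' @examples
#' a <- assembly(c(chr1 = strrep("ACGT", 300)), "toy")
#' mk <- generate_markers(a)
#' hits <- data.frame(qseqid = mk$marker_id[1:6], sseqid = "scf1",
#'                    sstart = mk$start[1:6] + 1, length = 100, pident = 99)
#' p <- paint(a, list(spX = hits))
#' p$blocks
#' @export
paint <- function(x, hit_tables, marker_len = 100L, min_aln_len = 50L,
                  min_run = 5L, drop_n = TRUE, require_collinear = FALSE) {
  stopifnot(inherits(x, "assembly"))
  if (is.null(names(hit_tables)) || anyDuplicated(names(hit_tables)))
    stop("hit_tables must be a uniquely named list (species labels)")
  markers <- generate_markers(x, marker_len = marker_len, drop_n = drop_n)
  blocks <- list(); stats <- list()
  for (sp in names(hit_tables)) {
    raw <- hit_tables[[sp]]
    best <- select_best_hits(raw, markers, sp)
    filt <- filter_hits(best, min_aln_len = min_aln_len)
    bl <- chain_markers(filt, min_run = min_run,
                        require_collinear = require_collinear,
                        marker_len = marker_len)
    blocks[[sp]] <- bl
    stats[[sp]] <- data.frame(
      species = sp, n_raw_hits = nrow(raw),
      n_unknown_qseqid = attr(best, "n_unknown"),
      n_best = nrow(best), n_retained = nrow(filt),
      n_markers_in_blocks = sum(bl$marker_count), n_blocks = nrow(bl),
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (is.null(blocks)) blocks <- chain_markers(
    data.frame(species = character(0), query_chrom = character(0),
               tile = integer(0), target_scaffold = character(0),
               target_start = numeric(0), aln_length = numeric(0)))
  blocks <- blocks[order(blocks$species, blocks$query_chrom,
                         blocks$first_index), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(
    assembly_name = x$name,
    species = names(hit_tables),
    blocks = blocks,
    markers = markers,
    n_markers = nrow(markers),
    stats = do.call(rbind, c(stats, list(make.row.names = FALSE))),
    params = list(marker_len = as.integer(marker_len),
                  min_aln_len = as.integer(min_aln_len),
                  min_run = as.integer(min_run), drop_n = drop_n,
                  require_collinear = require_collinear)),
    class = "painting")
}

#' @export
print.painting <- function(x, ...) {
  cat(sprintf("<painting> query %s: %d markers, %d species, %d blocks\n",
              x$assembly_name, x$n_markers, length(x$species),
              nrow(x$blocks)))
  cat(sprintf("  params: marker_len=%d, min_aln_len=%d, min_run=%d, drop_n=%s\n",
              x$params$marker_len, x$params$min_aln_len, x$params$min_run,
              x$params$drop_n))
  invisible(x)
}

#' @export
summary.painting <- function(object, ...) {
  print(object)
  cat("\nPer-species retention:\n")
  print(object$stats, row.names = FALSE)
  invisible(object$stats)
}
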