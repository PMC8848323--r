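# Karyotype curation: marker-vote assignment of scaffolds to chromosomes,
# macro/micro classification by length, and detection/splitting of
# artificially merged microchromosome scaffolds via composition shifts at
# candidate junctions.

#' Assign scaffolds to chromosomes by marker majority vote
#'
#' Chromosome-linked gene-marker hits vote for the source chromosome of
#' each scaffold; the majority label wins. A scaffold is flagged ambiguous
#' when its top two tallies are equal or the top tally is below
#' `min_votes`. Assigned macro (and micro) scaffolds are then renumbered
#' 1..n by descending scaffold length within their class.
#'
#' @param marker_hits hit table data.frame (as from [read_hit_table]):
#'   `qseqid` = marker id, `sseqid` = scaffold.
#' @param marker_to_chrom named character vector (marker id -> source
#'   chromosome label) or a two-column data.frame (`marker_id`, `chrom`).
#' @param x the [assembly] being assigned (scaffold lengths).
#' @param min_votes minimum winning tally for an unambiguous assignment.
#' @param macro_threshold,micro_min length thresholds passed to
#'   [classify_macro_micro].
#' @return object of class `"chromosome_assignment"`: list with `table`
#'   (data.frame: `scaffold`, `length`, `source_label`, `class`,
#'   `chrom_label`, `votes_top`, `ambiguous`), `evidence`
#'   (scaffold x label tally matrix) and `n_unknown_markers`.
#' @export
assign_chromosomes <- function(marker_hits, marker_to_chrom, x,
                               min_votes = 2L, macro_threshold = 5e7,
                               micro_min = 8e6) {
  stopifnot(inherits(x, "assembly"))
  if (is.data.frame(marker_to_chrom))
    marker_to_chrom <- stats::setNames(as.character(marker_to_chrom[[2]]),
                                       marker_to_chrom[[1]])
  lab <- marker_to_chrom[marker_hits$qseqid]
  n_unknown <- sum(is.na(lab))
  keep <- !is.na(lab)
  if (!any(keep)) stop("no assignable evidence: no marker hit matches the marker map")
  tab <- table(scaffold = marker_hits$sseqid[keep], label = lab[keep])
  lens <- seq_lengths(x)
  unknown_scf <- setdiff(rownames(tab), names(lens))
  if (length(unknown_scf))
    stop("hits reference scaffolds absent from the assembly: ",
         paste(unknown_scf, collapse = ", "))
  rows <- lapply(rownames(tab), function(s) {
    v <- tab[s, ]
    o <- order(-v, colnames(tab))
    top <- v[o[1]]
    tie <- length(v) > 1 && v[o[2]] == top
    data.frame(scaffold = s, length = unname(lens[s]),
               source_label = colnames(tab)[o[1]],
               votes_top = as.integer(top),
               ambiguous = tie || top < min_votes,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$source_label[df$ambiguous] <- NA_character_
  # conflict check: two labels whose majority scaffold coincides, where the
  # weaker claimant has substantial support (>= min_votes and at least half
  # the stronger tally), contradict each other. Stray minority markers on
  # another chromosome's scaffold are tolerated; exact ties are handled by
  # the scaffold-level ambiguity flag instead.
  lab_best <- apply(tab, 2, function(v) rownames(tab)[which.max(v)])
  lab_top <- apply(tab, 2, max)
  for (s in unique(lab_best)) {
    claimants <- names(lab_best)[lab_best == s]
    if (length(claimants) < 2) next
    v <- sort(lab_top[claimants], decreasing = TRUE)
    if (v[2] < v[1] && v[2] >= min_votes && 2 * v[2] >= v[1])
      stop("conflicting labels share a majority scaffold (", s, "): ",
           paste(names(v)[1:2], collapse = ", "))
  }
  df$class <- unname(classify_macro_micro(stats::setNames(df$length,
                                                          df$scaffold),
                                          macro_threshold, micro_min))
  # renumber assigned scaffolds within class by descending length
  df$chrom_label <- NA_character_
  for (cl in c("macro", "micro")) {
    sel <- which(df$class == cl & !df$ambiguous)
    sel <- sel[order(-df$length[sel])]
    if (length(sel))
      df$chrom_label[sel] <- paste0(cl, seq_along(sel))
  }
  df <- df[order(match(df$class, c("macro", "micro", "unplaced")),
                 -df$length), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(table = df, evidence = unclass(tab),
                 n_unknown_markers = n_unknown),
            class = "chromosome_assignment")
}

#' @export
print.chromosome_assignment <- function(x, ...) {
  cat("<chromosome_assignment>\n")
  print(x$table, row.names = FALSE)
  if (x$n_unknown_markers > 0)
    cat(sprintf("(%d marker hits without a map entry were ignored)\n",
                x$n_unknown_markers))
  invisible(x)
}

#' Classify scaffolds as macro-, microchromosome or unplaced by length
#'
#' Macrochromosome: length >= `macro_threshold` (inclusive, the squamate
#' 50-Mb convention). Microchromosome candidate: `micro_min` < length <
#' `macro_threshold` (the lower bound exclusive, matching the >8 Mb
#' candidacy rule). Anything at or below `micro_min` is `"unplaced"`.
#'
#' @param lengths named numeric vector scaffold -> bp.
#' @param macro_threshold macro boundary in bp.
#' @param micro_min micro candidacy lower bound in bp.
#' @return named character vector of classes.
#' @export
classify_macro_micro <- function(lengths, macro_threshold = 5e7,
                                 micro_min = 8e6) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  out <- ifelse(lengths >= macro_threshold, "macro",
                ifelse(lengths > micro_min, "micro", "unplaced"))
  stats::setNames(out, names(lengths))
}

#' Detect candidate junctions from N-gap runs
#'
#' Runs of at least `min_gap` consecutive `N` bases mark scaffold joins
#' (assembly gaps); the midpoint of each qualifying run is returned as a
#' candidate breakpoint. Used when explicit sub-scaffold junction metadata
#' is unavailable.
#'
#' @param x an [assembly].
#' @param scaffold scaffold name.
#' @param min_gap minimum N-run length (default 50).
#' @return numeric vector of 0-based junction positions.
#' @export
find_gap_junctions <- function(x, scaffold, min_gap = 50L) {
  stopifnot(inherits(x, "assembly"))
  s <- x$seq[[scaffold]]
  if (is.null(s)) stop("unknown scaffold: ", scaffold)
  ir <- Biostrings::matchPattern("N", s)
  if (length(ir) == 0L) return(numeric(0))
  r <- IRanges::reduce(methods::as(ir, "IRanges"))
  r <- r[IRanges::width(r) >= min_gap]
  # midpoint, 0-based
  floor((IRanges::start(r) - 1 + IRanges::end(r)) / 2)
}

#' Score candidate breakpoints by composition shifts
#'
#' For each candidate junction, the mean GC% and mean repeat fraction of up
#' to `flank_windows` whole windows on each side are compared:
#' `delta_gc = |right - left|`, `delta_repeat` likewise, and `local_gd` is
#' the mean genic fraction of the two windows straddling the junction. A
#' composite shift score standardizes each delta across the candidates
#' (z-scores) and sums them; a candidate with fewer than one whole window
#' on a side is scored with what is available and flagged.
#'
#' @param scaffold scaffold name.
#' @param candidates numeric vector of 0-based junction positions.
#' @param track a `window_track` covering the scaffold.
#' @param flank_windows windows per side (default 3).
#' @return data.frame of class `"breakpoint_scores"`: `scaffold`,
#'   `position`, `delta_gc`, `delta_repeat`, `local_gd`, `z_gc`,
#'   `z_repeat`, `shift_score`, `flagged`, `chosen`.
#' @export
score_breakpoints <- function(scaffold, candidates, track,
                              flank_windows = 3L) {
  win <- track[track$chrom == scaffold, , drop = FALSE]
  if (nrow(win) == 0L) stop("track has no windows for scaffold ", scaffold)
  win <- win[order(win$start), , drop = FALSE]
  if (any(candidates <= 0 | candidates >= max(win$end)))
    stop("candidate positions must lie strictly inside the scaffold")
  one <- function(pos) {
    li <- which(win$end <= pos)
    ri <- which(win$start >= pos)
    flagged <- length(li) < 1L || length(ri) < 1L
    li <- utils::tail(li, flank_windows)
    ri <- utils::head(ri, flank_windows)
    dgc <- if (length(li) && length(ri))
      abs(mean(win$gc_pct[ri], na.rm = TRUE) -
          mean(win$gc_pct[li], na.rm = TRUE)) else NA_real_
    drep <- if (length(li) && length(ri))
      abs(mean(win$repeat_frac[ri]) - mean(win$repeat_frac[li])) else NA_real_
    straddle <- c(utils::tail(li, 1), utils::head(ri, 1))
    lgd <- if (length(straddle)) mean(win$gene_frac[straddle]) else NA_real_
    flagged <- flagged || length(li) < flank_windows ||
      length(ri) < flank_windows
    c(dgc = dgc, drep = drep, lgd = lgd, flagged = as.numeric(flagged))
  }
  sc <- t(vapply(candidates, one, c(dgc = 0, drep = 0, lgd = 0, flagged = 0)))
  zs <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }
  z_gc <- zs(sc[, "dgc"]); z_rep <- zs(sc[, "drep"])
  out <- data.frame(scaffold = scaffold, position = candidates,
                    delta_gc = sc[, "dgc"], delta_repeat = sc[, "drep"],
                    local_gd = sc[, "lgd"], z_gc = z_gc, z_repeat = z_rep,
                    shift_score = z_gc + z_rep,
                    flagged = sc[, "flagged"] > 0, chosen = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("breakpoint_scores", "data.frame")
  out
}

#' Split a scaffold at the best-supported breakpoint
#'
#' Candidates whose composite shift score exceeds `shift_z_min` carry the
#' abrupt-composition-shift signature; among them the one with the lowest
#' local genic density is chosen (splitting where gene models are least
#' likely to be disrupted). The scaffold is replaced in place by
#' `<scaffold>_L` and `<scaffold>_R`. Total length and base content are
#' conserved exactly. If no candidate passes, an error is raised rather
#' than splitting silently.
#'
#' @param x an [assembly].
#' @param scaffold scaffold to split.
#' @param scored a `breakpoint_scores` data.frame from
#'   [score_breakpoints].
#' @param shift_z_min minimum composite shift score (default 2).
#' @return list with `assembly` (curated) and `report` (list: `scaffold`,
#'   `position`, `scores` with the chosen row flagged).
#' @export
split_scaffold <- function(x, scaffold, scored, shift_z_min = 2) {
  stopifnot(inherits(x, "assembly"))
  s <- x$seq[[scaffold]]
  if (is.null(s)) stop("unknown scaffold: ", scaffold)
  pass <- which(!is.na(scored$shift_score) &
                scored$shift_score > shift_z_min & !is.na(scored$local_gd))
  if (length(pass) == 0L)
    stop("no supported breakpoint: no candidate has shift score > ",
         shift_z_min)
  chosen <- pass[which.min(scored$local_gd[pass])]
  pos <- scored$position[chosen]
  scored$chosen <- seq_len(nrow(scored)) == chosen
  L <- length(s)
  if (pos <= 0 || pos >= L) stop("breakpoint position outside scaffold")
  chr <- as.character(x$seq)
  names(chr) <- names(x$seq)
  i <- match(scaffold, names(chr))
  left <- substr(chr[i], 1, pos)
  right <- substr(chr[i], pos + 1, L)
  newchr <- append(chr[-i],
                   stats::setNames(c(left, right),
                                   paste0(scaffold, c("_L", "_R"))),
                   after = i - 1)
  curated <- assembly(newchr, name = paste0(x$name, "_curated"))
  list(assembly = curated,
       report = list(scaffold = scaffold, position = pos, scores = scored))
}
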