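# Per-window composition tracks (GC%, genic fraction, repeat fraction) and
# macro/micro rank-sum contrasts.

#' Tile an assembly into analysis windows
#'
#' Windows of `window_size` bp tile each chromosome from 0; a trailing
#' partial window is kept only if its length is at least
#' `min_final_frac * window_size`. `effective_len` counts non-N bases.
#'
#' @param x an [assembly].
#' @param window_size window size in bp (default 1 Mb, minimum 1 kb).
#' @param min_final_frac minimum trailing-window fraction to keep.
#' @return data.frame with columns `chrom`, `index`, `start`, `end`,
#'   `effective_len`.
#' @export
make_windows <- function(x, window_size = 1e6, min_final_frac = 0.5) {
  stopifnot(inherits(x, "assembly"))
  if (window_size < 1000) stop("window_size must be >= 1000")
  window_size <- as.integer(window_size)
  pieces <- vector("list", length(x$seq))
  for (i in seq_along(x$seq)) {
    L <- Biostrings::width(x$seq)[i]
    n_full <- L %/% window_size
    rem <- L %% window_size
    starts <- (seq_len(n_full) - 1L) * window_size
    ends <- starts + window_size
    if (rem >= min_final_frac * window_size) {
      starts <- c(starts, n_full * window_size)
      ends <- c(ends, L)
    }
    if (!length(starts)) next
    v <- Biostrings::Views(x$seq[[i]], start = starts + 1L, width = ends - starts)
    ncount <- Biostrings::letterFrequency(v, "N")[, 1]
    pieces[[i]] <- data.frame(chrom = names(x$seq)[i],
                              index = seq_along(starts) - 1L,
                              start = starts, end = ends,
                              effective_len = (ends - starts) - ncount,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), index = integer(0),
                      start = numeric(0), end = numeric(0),
                      effective_len = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  out
}

#' GC percentage of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from the
#' denominator. Returns `NA` when no A/C/G/T base is present.
#'
#' @param sequence character string, `DNAString`, or `Views` slice.
#' @return GC percent in `[0, 100]`, or `NA_real_`.
#' @examples
#' gc_content("GGCC")   # 100
#' gc_content("ACGTN")  # 50
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  f <- Biostrings::letterFrequency(sequence, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  100 * (f[["C"]] + f[["G"]]) / denom
}

#' Fraction of a window covered by intervals
#'
#' Overlapping intervals are merged before counting, so the result is
#' invariant to interval order and to splitting intervals at arbitrary
#' points. Intervals are clipped to the window.
#'
#' @param intervals data.frame of 0-based half-open intervals with columns
#'   `seq_id`, `start`, `end` (only rows on `chrom` are used).
#' @param chrom,start,end the window (0-based half-open).
#' @return covered fraction in `[0, 1]`.
#' @examples
#' iv <- data.frame(seq_id = "c", start = c(0, 400), end = c(600, 800))
#' coverage_fraction(iv, "c", 0, 1000)  # 0.8
#' @export
coverage_fraction <- function(intervals, chrom, start, end) {
  stopifnot(end > start)
  iv <- intervals[intervals$seq_id == chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  m <- merge_intervals(iv$start, iv$end)
  covered_bases(m, start, end) / (end - start)
}

#' Validate intervals against an assembly
#'
#' @param intervals interval data.frame (`seq_id`, `start`, `end`).
#' @param x an [assembly].
#' @param what label used in error messages.
#' @return invisibly `TRUE`; errors on out-of-range intervals or unknown
#'   sequence ids.
#' @export
validate_intervals <- function(intervals, x, what = "interval") {
  if (nrow(intervals) == 0L) return(invisible(TRUE))
  lens <- seq_lengths(x)
  unknown <- setdiff(unique(intervals$seq_id), names(lens))
  if (length(unknown))
    stop(what, "s reference unknown sequences: ",
         paste(unknown, collapse = ", "))
  L <- lens[intervals$seq_id]
  bad <- intervals$start < 0 | intervals$end > L |
    intervals$start >= intervals$end
  if (any(bad))
    stop(what, " out of range on ", intervals$seq_id[which(bad)[1]],
         ": [", intervals$start[which(bad)[1]], ", ",
         intervals$end[which(bad)[1]], ")")
  invisible(TRUE)
}

#' Build a per-window composition track
#'
#' Computes GC% (N-excluded), genic fraction and repeat fraction for each
#' window, and labels windows by chromosome class.
#'
#' @param x an [assembly].
#' @param genes,repeats interval data.frames (may be `NULL` for none).
#' @param class_map named character vector chromosome -> class
#'   (`"macro"`, `"micro"` or `"unassigned"`); chromosomes absent from the
#'   map are `"unassigned"`. All names must exist in the assembly.
#' @param window_size,min_final_frac see [make_windows].
#' @return data.frame of class `"window_track"` with columns `chrom`,
#'   `class`, `index`, `start`, `end`, `effective_len`, `gc_pct`,
#'   `gene_frac`, `gene_count` (genes overlapping the window — the
#'   non-default count view of gene density), `repeat_frac`.
#' @export
build_track <- function(x, genes = NULL, repeats = NULL, class_map = NULL,
                        window_size = 1e6, min_final_frac = 0.5) {
  stopifnot(inherits(x, "assembly"))
  if (!is.null(class_map)) {
    unknown <- setdiff(names(class_map), names(x$seq))
    if (length(unknown))
      stop("class_map names chromosomes absent from the assembly: ",
           paste(unknown, collapse = ", "))
  }
  empty <- data.frame(seq_id = character(0), start = numeric(0),
                      end = numeric(0))
  if (is.null(genes)) genes <- empty
  if (is.null(repeats)) repeats <- empty
  validate_intervals(genes, x, "gene interval")
  validate_intervals(repeats, x, "repeat interval")
  win <- make_windows(x, window_size, min_final_frac)
  win$class <- "unassigned"
  if (!is.null(class_map)) {
    hit <- win$chrom %in% names(class_map)
    win$class[hit] <- unname(class_map[win$chrom[hit]])
  }
  win$gc_pct <- NA_real_
  win$gene_frac <- 0
  win$gene_count <- 0L
  win$repeat_frac <- 0
  # merged intervals per chromosome, computed once
  gmerged <- lapply(split(genes, genes$seq_id),
                    function(g) merge_intervals(g$start, g$end))
  rmerged <- lapply(split(repeats, repeats$seq_id),
                    function(g) merge_intervals(g$start, g$end))
  for (chrom in unique(win$chrom)) {
    sel <- which(win$chrom == chrom)
    v <- Biostrings::Views(x$seq[[chrom]], start = win$start[sel] + 1L,
                           width = win$end[sel] - win$start[sel])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(f)
    gc <- ifelse(denom == 0, NA_real_,
                 100 * (f[, "C"] + f[, "G"]) / denom)
    win$gc_pct[sel] <- gc
    gm <- gmerged[[chrom]]; rm_ <- rmerged[[chrom]]
    for (k in seq_along(sel)) {
      i <- sel[k]
      wlen <- win$end[i] - win$start[i]
      if (!is.null(gm))
        win$gene_frac[i] <- covered_bases(gm, win$start[i], win$end[i]) / wlen
      if (!is.null(rm_))
        win$repeat_frac[i] <- covered_bases(rm_, win$start[i], win$end[i]) / wlen
    }
  }
  gsub_chrom <- split(genes, genes$seq_id)
  for (chrom in names(gsub_chrom)) {
    sel <- which(win$chrom == chrom)
    g <- gsub_chrom[[chrom]]
    for (i in sel)
      win$gene_count[i] <- sum(g$start < win$end[i] & g$end > win$start[i])
  }
  out <- win[, c("chrom", "class", "index", "start", "end", "effective_len",
                 "gc_pct", "gene_frac", "gene_count", "repeat_frac")]
  attr(out, "window_size") <- attr(win, "window_size")
  class(out) <- c("window_track", "data.frame")
  out
}

#' Write a window track as TSV
#' @param track a `window_track`.
#' @param path output file.
#' @export
write_track_tsv <- function(track, path) {
  write_tsv_with_header(as.data.frame(track), path,
                        c("per-window composition track",
                          "coordinates 0-based half-open; gc_pct excludes N"))
}

# Exact two-sided rank-sum p-value by enumeration over group assignments,
# using mid-ranks so ties are handled. Feasible for n1, n2 <= 8.
exact_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)           # mid-ranks
  n1 <- length(x); n <- length(vals)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combs], nrow = n1))
  # two-sided: as or more extreme in |W - E[W]|
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Compare macro- and microchromosome windows for one metric
#'
#' Two-sided Wilcoxon rank-sum test of the macro-class windows against the
#' micro-class windows. When both groups have at most 8 usable windows the
#' p-value is computed by exact enumeration over group assignments with
#' mid-ranks; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used (via [stats::wilcox.test]).
#' Both statistic conventions are reported: `W_macro` is the rank sum of
#' the macro group, `U = W_macro - n1*(n1+1)/2` its Mann-Whitney form (the
#' `W` printed by mainstream statistical environments).
#'
#' @param track a `window_track`.
#' @param metric one of `"gene_frac"`, `"gc_pct"`, `"repeat_frac"`, or
#'   the count-scale `"gene_count"`.
#' @param exact_max largest per-group size for the exact enumeration path.
#' @return list of class `"group_comparison"`: `metric`, `n_macro`,
#'   `n_micro`, `mean_macro`, `mean_micro`, `median_macro`, `median_micro`,
#'   `W_macro`, `U`, `p_value`, `method`.
#' @export
compare_macro_micro <- function(track,
                                metric = c("gene_frac", "gc_pct",
                                           "repeat_frac", "gene_count"),
                                exact_max = 8L) {
  metric <- match.arg(metric)
  x <- track[[metric]][track$class == "macro"]
  y <- track[[metric]][track$class == "micro"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both classes need at least one usable window (macro: ",
         length(x), ", micro: ", length(y), ")")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W_macro <- sum(r[seq_len(n1)])
  U <- W_macro - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- exact_ranksum_p(x, y)
    method <- "exact enumeration (mid-ranks)"
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    p <- wt$p.value
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  structure(list(metric = metric, n_macro = n1, n_micro = n2,
                 mean_macro = mean(x), mean_micro = mean(y),
                 median_macro = stats::median(x),
                 median_micro = stats::median(y),
                 W_macro = W_macro, U = U, p_value = p, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Macro vs micro windows, metric %s\n", x$metric))
  cat(sprintf("  n = %d / %d;  mean = %.4g / %.4g;  median = %.4g / %.4g\n",
              x$n_macro, x$n_micro, x$mean_macro, x$mean_micro,
              x$median_macro, x$median_micro))
  cat(sprintf("  rank sum (macro) W = %.1f;  U = %.1f;  two-sided p = %.3g\n",
              x$W_macro, x$U, x$p_value))
  cat(sprintf("  method: %s\n", x$method))
  invisible(x)
}
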