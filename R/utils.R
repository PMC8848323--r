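# Internal helpers shared across modules.

# Derive a reproducible substream seed from a base seed and a stage name.
# Keeps results < 2^31 so set.seed() accepts them on all platforms.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 10007) %% .Machine$integer.max)
}

# Truncated normal draws by rejection; sd = 0 degenerates to the clamped mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n, 16L), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Merge possibly-overlapping half-open intervals given as start/end vectors.
# Returns a list(start=, end=) of disjoint sorted intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Bases of [qs, qe) covered by merged intervals, clipped to [qs, qe).
covered_bases <- function(merged, qs, qe) {
  if (length(merged$start) == 0L) return(0)
  ov <- pmin(merged$end, qe) - pmax(merged$start, qs)
  sum(ov[ov > 0])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV writer with "#"-prefixed metadata header lines (coordinate convention,
# package version, parameters).
write_tsv_with_header <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("synpaint"))
  writeLines(c(sprintf("# synpaint %s", ver), paste0("# ", meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}
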