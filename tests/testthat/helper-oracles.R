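# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (per-base masks, linear scans) so they cannot share bugs with the
# implementation they check.

rand_seq <- function(len, gc = 0.4, n_prob = 0) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p)
  if (n_prob > 0) {
    nn <- runif(len) < n_prob
    b[nn] <- "N"
  }
  paste(b, collapse = "")
}

rand_assembly <- function(n_chrom = 3, len_range = c(200, 2000), gc = 0.4,
                          n_prob = 0, prefix = "chr") {
  lens <- sample(seq(len_range[1], len_range[2]), n_chrom, replace = TRUE)
  seqs <- vapply(lens, rand_seq, "", gc = gc, n_prob = n_prob)
  names(seqs) <- paste0(prefix, seq_len(n_chrom))
  assembly(seqs, name = "random")
}

# Naive GC: character counting, N excluded from the denominator.
naive_gc <- function(s) {
  b <- strsplit(s, "")[[1]]
  acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  100 * sum(b %in% c("G", "C")) / acgt
}

# Per-base boolean-mask coverage of [start, end) by intervals on chrom.
mask_coverage <- function(intervals, chrom, start, end) {
  iv <- intervals[intervals$seq_id == chrom, , drop = FALSE]
  mask <- logical(end - start)
  for (i in seq_len(nrow(iv))) {
    s <- max(iv$start[i], start); e <- min(iv$end[i], end)
    if (e > s) mask[(s - start + 1):(e - start)] <- TRUE
  }
  sum(mask) / (end - start)
}

# Brute-force run-length chaining oracle: linear scan over (tile, scaffold)
# pairs of one chromosome, emitting (first, last, count, scaffold) for every
# maximal run of consecutive tiles on one scaffold with count >= min_run.
rle_blocks <- function(tiles, scaffolds, min_run = 5) {
  o <- order(tiles)
  tiles <- tiles[o]; scaffolds <- scaffolds[o]
  out <- list()
  i <- 1
  while (i <= length(tiles)) {
    j <- i
    while (j < length(tiles) && tiles[j + 1] == tiles[j] + 1 &&
           scaffolds[j + 1] == scaffolds[j]) j <- j + 1
    if (j - i + 1 >= min_run)
      out[[length(out) + 1]] <- data.frame(first = tiles[i], last = tiles[j],
                                           count = j - i + 1,
                                           scaffold = scaffolds[i])
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(first = integer(0), last = integer(0), count = integer(0),
               scaffold = character(0))
}

# Build a retained-hit data.frame directly (bypassing hit-table I/O) for
# chaining tests: one row per (tile, scaffold) on a single chromosome.
retained_frame <- function(tiles, scaffolds, chrom = "chr1", species = "sp",
                           target_start = NULL, aln = 100) {
  data.frame(marker_id = sprintf("%s_%06d", chrom, tiles),
             query_chrom = chrom, tile = tiles, species = species,
             target_scaffold = scaffolds,
             target_start = target_start %||% (tiles * 100),
             aln_length = aln, pident = 99, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny simulated painting scenario used by several tests: returns the query
# simulation, hit tables and ground truth for a fused-micros + fissioned
# macro target.
tiny_scenario <- function(seed, n_macro = 2, n_micro = 4,
                          macro_len = 2e6, micro_len = 8e5,
                          drop_rate = 0, spurious_rate = 0) {
  spec <- karyotype_spec(n_macro, n_micro, macro_len, micro_len)
  sim <- simulate_query(spec, composition_params(), seed = seed,
                        window_size = 1e5)
  ops <- list(fusion("micro1", "micro2"),
              fission("macro1", macro_len / 2))
  tr <- apply_rearrangements(sim$assembly, ops)
  mk <- generate_markers(sim$assembly)
  hits <- emit_hits(mk, tr$truth, drop_rate = drop_rate,
                    spurious_rate = spurious_rate, seed = seed)
  list(sim = sim, markers = mk, truth = tr$truth, target = tr$assembly,
       hits = hits)
}
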