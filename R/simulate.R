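# Synthetic genomes with macro/micro composition structure, rearranged
# target genomes with a ground-truth homology map, and noisy marker hit
# tables. Every stage of the pipeline is testable against this generator.

#' Karyotype specification for the simulator
#'
#' Defaults describe the desk-scale scenario: 6 macrochromosomes of 20 Mb
#' and 11 microchromosomes of 8 Mb (208 Mb total), enough for >200 windows
#' of 1 Mb while staying fast to generate.
#'
#' @param n_macro,n_micro chromosome counts per class.
#' @param macro_length,micro_length lengths in bp (recycled to the counts).
#' @return list of class `"karyotype_spec"`.
#' @export
karyotype_spec <- function(n_macro = 6L, n_micro = 11L,
                           macro_length = 2e7, micro_length = 8e6) {
  macro_lengths <- rep_len(macro_length, n_macro)
  micro_lengths <- rep_len(micro_length, n_micro)
  if (n_macro > 0 && n_micro > 0 && min(macro_lengths) <= max(micro_lengths))
    stop("every macro length must exceed every micro length")
  structure(list(n_macro = n_macro, n_micro = n_micro,
                 macro_lengths = macro_lengths,
                 micro_lengths = micro_lengths),
            class = "karyotype_spec")
}

#' Per-class composition parameters
#'
#' Defaults are the per-1-Mb-window class distributions of a squamate
#' genome with distinct macro/micro composition: GC% mean 35.9 (SD 1.2) for
#' macro- and 38.5 (SD 2.8) for microchromosomes; genic fraction 0.19
#' (SD 0.14) vs 0.27 (SD 0.16); repeat fraction 0.446 (SD 0.056) vs 0.394
#' (SD 0.10). Per-window draws are truncated to the valid range.
#'
#' @param macro,micro named lists with elements `gc_mean`, `gc_sd` (in %),
#'   `gene_mean`, `gene_sd`, `repeat_mean`, `repeat_sd` (fractions).
#' @return list of class `"composition_params"`.
#' @export
composition_params <- function(
    macro = list(gc_mean = 35.9, gc_sd = 1.2,
                 gene_mean = 0.19, gene_sd = 0.14,
                 repeat_mean = 0.446, repeat_sd = 0.056),
    micro = list(gc_mean = 38.5, gc_sd = 2.8,
                 gene_mean = 0.27, gene_sd = 0.16,
                 repeat_mean = 0.394, repeat_sd = 0.10)) {
  for (cl in list(macro, micro)) {
    stopifnot(cl$gc_mean >= 0, cl$gc_mean <= 100,
              cl$gene_mean >= 0, cl$gene_mean <= 1,
              cl$repeat_mean >= 0, cl$repeat_mean <= 1)
  }
  structure(list(macro = macro, micro = micro),
            class = "composition_params")
}

# Emit one window of i.i.d. bases at the given GC probability.
random_window_bases <- function(wlen, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, wlen, replace = TRUE, prob = p)
  charToRaw("ACGT")[idx]
}

# Place non-overlapping intervals inside [ws, we) until target_frac of the
# window is covered within tol (as a fraction of window length). Interval
# lengths are uniform on [lmin, lmax]; the final interval is shortened to
# land near the target.
place_in_window <- function(ws, we, target_frac, lmin, lmax, tol = 0.005) {
  wlen <- we - ws
  need <- target_frac * wlen
  if (target_frac > 1 - tol)
    stop("infeasible coverage fraction ", target_frac, " for one annotation type")
  covered <- 0
  starts <- numeric(0); ends <- numeric(0)
  fails <- 0L
  while (covered < need - tol * wlen && fails < 500L) {
    L <- round(stats::runif(1, lmin, lmax))
    if (L > need - covered) L <- max(1, ceiling(need - covered))
    if (L > wlen) L <- wlen
    s <- floor(stats::runif(1, ws, we - L + 1))
    e <- s + L
    if (!any(s < ends & e > starts)) {
      starts <- c(starts, s); ends <- c(ends, e)
      covered <- covered + L
      fails <- 0L
    } else fails <- fails + 1L
  }
  list(start = starts, end = ends)
}

#' Simulate a query genome with macro/micro composition structure
#'
#' Per 1-Mb window the target GC%, genic fraction and repeat fraction are
#' drawn from truncated normals with the window's class parameters; bases
#' are emitted i.i.d. at the window's GC probability, and non-overlapping
#' gene (1-50 kb) and repeat (0.1-5 kb) intervals are placed uniformly
#' until each window's target fraction is met within 0.5 percentage
#' points. All randomness flows from `seed` through named substreams, so
#' the genome is unchanged by downstream draws.
#'
#' @param spec a [karyotype_spec].
#' @param params a [composition_params].
#' @param seed integer seed.
#' @param window_size parameter-draw window in bp.
#' @return list of class `"sim_query"`: `assembly`, `genes`, `repeats`
#'   (interval data.frames), `class_map` (named character vector).
#' @export
simulate_query <- function(spec = karyotype_spec(),
                           params = composition_params(), seed,
                           window_size = 1e6) {
  stopifnot(inherits(spec, "karyotype_spec"),
            inherits(params, "composition_params"))
  if (missing(seed)) stop("seed is required")
  chroms <- c(if (spec$n_macro) paste0("macro", seq_len(spec$n_macro)),
              if (spec$n_micro) paste0("micro", seq_len(spec$n_micro)))
  lens <- c(spec$macro_lengths, spec$micro_lengths)
  classes <- rep(c("macro", "micro"), c(spec$n_macro, spec$n_micro))
  names(lens) <- names(classes) <- chroms

  # sequence substream: per-window GC draws, then bases
  set.seed(substream_seed(seed, "sequence"))
  seqs <- character(length(chroms))
  win_list <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    cl <- params[[classes[i]]]
    L <- lens[i]
    bounds <- unique(c(seq(0, L, by = window_size), L))
    ws <- bounds[-length(bounds)]; we <- bounds[-1]
    gc <- rtruncnorm(length(ws), cl$gc_mean, cl$gc_sd, 0, 100) / 100
    raws <- vector("list", length(ws))
    for (k in seq_along(ws))
      raws[[k]] <- random_window_bases(we[k] - ws[k], gc[k])
    seqs[i] <- rawToChar(unlist(raws))
    win_list[[i]] <- data.frame(chrom = chroms[i], ws = ws, we = we,
                                stringsAsFactors = FALSE)
  }
  names(seqs) <- chroms
  asm <- assembly(seqs, name = "sim_query")
  wins <- do.call(rbind, win_list)
  wins$class <- classes[wins$chrom]

  place_all <- function(stage, mean_field, sd_field, lmin, lmax, kind) {
    set.seed(substream_seed(seed, stage))
    pieces <- vector("list", nrow(wins))
    for (k in seq_len(nrow(wins))) {
      cl <- params[[wins$class[k]]]
      frac <- rtruncnorm(1, cl[[mean_field]], cl[[sd_field]], 0, 1)
      iv <- place_in_window(wins$ws[k], wins$we[k], frac, lmin, lmax)
      if (length(iv$start))
        pieces[[k]] <- data.frame(seq_id = wins$chrom[k], start = iv$start,
                                  end = iv$end, strand = ".", kind = kind,
                                  attrs = ".", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    if (is.null(out))
      out <- feature_frame(character(0), integer(0), integer(0),
                           character(0), kind, character(0))
    rownames(out) <- NULL
    out
  }
  genes <- place_all("genes", "gene_mean", "gene_sd", 1e3, 5e4, "gene")
  repeats <- place_all("repeats", "repeat_mean", "repeat_sd", 100, 5e3,
                       "repeat")
  structure(list(assembly = asm, genes = genes, repeats = repeats,
                 class_map = classes),
            class = "sim_query")
}

#' Rearrangement operations
#'
#' Constructors for the four karyotype rearrangement operations applied by
#' [apply_rearrangements]. All positions are 0-based offsets in the
#' *current* coordinates of the named chromosome at the time the op is
#' applied (ops are applied sequentially).
#'
#' * `fusion(a, b, orientation)` joins chromosome `b` onto the end of `a`
#'   (`orientation = "reverse"` reverse-complements `b` first); the fused
#'   chromosome is named `<a>+<b>`.
#' * `fission(a, position)` splits `a` into `<a>_L` (`[0, position)`) and
#'   `<a>_R`.
#' * `translocation(a, seg_start, seg_end, b, insert_pos)` moves
#'   `[seg_start, seg_end)` of `a` into `b` at `insert_pos`.
#' * `inversion(a, seg_start, seg_end)` reverse-complements
#'   `[seg_start, seg_end)` of `a` in place.
#'
#' @param a,b chromosome names.
#' @param orientation `"forward"` or `"reverse"`.
#' @param position,seg_start,seg_end,insert_pos 0-based coordinates.
#' @return a `rearrangement_op` list.
#' @name rearrangement_ops
NULL

#' @rdname rearrangement_ops
#' @export
fusion <- function(a, b, orientation = c("forward", "reverse")) {
  structure(list(type = "fusion", a = a, b = b,
                 orientation = match.arg(orientation)),
            class = "rearrangement_op")
}

#' @rdname rearrangement_ops
#' @export
fission <- function(a, position) {
  structure(list(type = "fission", a = a, position = position),
            class = "rearrangement_op")
}

#' @rdname rearrangement_ops
#' @export
translocation <- function(a, seg_start, seg_end, b, insert_pos) {
  structure(list(type = "translocation", a = a, seg_start = seg_start,
                 seg_end = seg_end, b = b, insert_pos = insert_pos),
            class = "rearrangement_op")
}

#' @rdname rearrangement_ops
#' @export
inversion <- function(a, seg_start, seg_end) {
  structure(list(type = "inversion", a = a, seg_start = seg_start,
                 seg_end = seg_end), class = "rearrangement_op")
}

# --- segment algebra -------------------------------------------------------
# A target chromosome is a list of segments; each segment is a row
# (q_chrom, q_start, q_end, strand) of query sequence. seg_len gives the
# target-side length of each segment.

seg_len <- function(segs) segs$q_end - segs$q_start

# Split a segment data.frame at target-offset pos; returns list(left, right).
cut_segments <- function(segs, pos) {
  lens <- seg_len(segs)
  cum <- cumsum(lens)
  total <- if (length(cum)) cum[length(cum)] else 0
  if (pos < 0 || pos > total) stop("position ", pos, " outside chromosome")
  if (pos == 0) return(list(left = segs[0, ], right = segs))
  if (pos == total) return(list(left = segs, right = segs[0, ]))
  i <- which(cum >= pos)[1]
  before <- if (i > 1) cum[i - 1] else 0
  off <- pos - before
  left <- segs[seq_len(i), , drop = FALSE]
  right <- segs[seq(i, nrow(segs)), , drop = FALSE]
  if (off < lens[i]) {
    if (left$strand[i] == "+") {
      left$q_end[i] <- left$q_start[i] + off
      right$q_start[1] <- right$q_start[1] + off
    } else {
      # reverse segment: the first `off` target bases come from the query end
      left$q_start[i] <- left$q_end[i] - off
      right$q_end[1] <- right$q_end[1] - off
    }
  } else {
    right <- right[-1, , drop = FALSE]
  }
  rownames(left) <- rownames(right) <- NULL
  list(left = left, right = right)
}

flip_segments <- function(segs) {
  if (nrow(segs) == 0L) return(segs)
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  rownames(segs) <- NULL
  segs
}

#' Apply rearrangement operations and derive the ground-truth homology map
#'
#' Operations are applied sequentially to a working copy of the query
#' genome. Sequence content is conserved exactly (no gain or loss of
#' bases); the returned truth map records, for every target interval, the
#' query interval and orientation it derives from, and tiles every query
#' base exactly once. Both invariants are asserted on every call.
#'
#' @param x the query [assembly].
#' @param ops list of [rearrangement_ops] (may be empty for an identity
#'   target).
#' @return list with `assembly` (the target genome) and `truth`
#'   (data.frame: `target_chrom`, `t_start`, `t_end`, `q_chrom`,
#'   `q_start`, `q_end`, `strand`).
#' @export
apply_rearrangements <- function(x, ops = list()) {
  stopifnot(inherits(x, "assembly"))
  lens <- seq_lengths(x)
  state <- lapply(names(lens), function(ch)
    data.frame(q_chrom = ch, q_start = 0, q_end = unname(lens[ch]),
               strand = "+", stringsAsFactors = FALSE))
  names(state) <- names(lens)
  for (op in ops) {
    if (!inherits(op, "rearrangement_op")) stop("ops must be rearrangement_op")
    need <- switch(op$type,
                   fusion = c(op$a, op$b),
                   fission = op$a,
                   translocation = c(op$a, op$b),
                   inversion = op$a)
    missing_ch <- setdiff(need, names(state))
    if (length(missing_ch))
      stop(op$type, " references unknown chromosome: ",
           paste(missing_ch, collapse = ", "))
    if (op$type == "fusion") {
      bseg <- state[[op$b]]
      if (op$orientation == "reverse") bseg <- flip_segments(bseg)
      merged <- rbind(state[[op$a]], bseg)
      state[[op$a]] <- NULL; state[[op$b]] <- NULL
      state[[paste0(op$a, "+", op$b)]] <- merged
    } else if (op$type == "fission") {
      cs <- cut_segments(state[[op$a]], op$position)
      if (nrow(cs$left) == 0L || nrow(cs$right) == 0L)
        stop("fission position must be strictly inside ", op$a)
      nm <- op$a
      state[[nm]] <- NULL
      state[[paste0(nm, "_L")]] <- cs$left
      state[[paste0(nm, "_R")]] <- cs$right
    } else if (op$type == "translocation") {
      if (op$seg_end <= op$seg_start)
        stop("translocation segment must be non-empty on ", op$a)
      cs1 <- cut_segments(state[[op$a]], op$seg_start)
      cs2 <- cut_segments(cs1$right, op$seg_end - op$seg_start)
      moved <- cs2$left
      state[[op$a]] <- rbind(cs1$left, cs2$right)
      ins <- cut_segments(state[[op$b]], op$insert_pos)
      state[[op$b]] <- rbind(ins$left, moved, ins$right)
    } else if (op$type == "inversion") {
      if (op$seg_end <= op$seg_start)
        stop("inversion segment must be non-empty on ", op$a)
      cs1 <- cut_segments(state[[op$a]], op$seg_start)
      cs2 <- cut_segments(cs1$right, op$seg_end - op$seg_start)
      state[[op$a]] <- rbind(cs1$left, flip_segments(cs2$left), cs2$right)
    }
  }
  # build sequences and truth map
  truth <- vector("list", length(state))
  seqs <- character(length(state))
  for (i in seq_along(state)) {
    segs <- state[[i]]
    rownames(segs) <- NULL
    lens_i <- seg_len(segs)
    t_end <- cumsum(lens_i)
    t_start <- t_end - lens_i
    truth[[i]] <- data.frame(target_chrom = names(state)[i],
                             t_start = t_start, t_end = t_end,
                             q_chrom = segs$q_chrom,
                             q_start = segs$q_start, q_end = segs$q_end,
                             strand = segs$strand, stringsAsFactors = FALSE)
    parts <- character(nrow(segs))
    for (k in seq_len(nrow(segs))) {
      sub <- Biostrings::subseq(x$seq[[segs$q_chrom[k]]],
                                start = segs$q_start[k] + 1,
                                end = segs$q_end[k])
      if (segs$strand[k] == "-") sub <- Biostrings::reverseComplement(sub)
      parts[k] <- as.character(sub)
    }
    seqs[i] <- paste0(parts, collapse = "")
  }
  names(seqs) <- names(state)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  target <- assembly(seqs, name = paste0(x$name, "_target"))
  # invariants: conservation and exact tiling of the query
  stopifnot(total_length(target) == total_length(x))
  for (ch in names(lens)) {
    q <- truth[truth$q_chrom == ch, , drop = FALSE]
    q <- q[order(q$q_start), , drop = FALSE]
    stopifnot(nrow(q) > 0, q$q_start[1] == 0,
              q$q_end[nrow(q)] == lens[[ch]],
              all(q$q_start[-1] == q$q_end[-nrow(q)]))
  }
  list(assembly = target, truth = truth)
}

#' Emit a marker hit table from a ground-truth map
#'
#' Each query marker is mapped through the truth map to its target
#' coordinate. Markers are dropped with probability `drop_rate`; with
#' probability `spurious_rate` a marker's hit is replaced by a spurious one
#' on a random wrong scaffold at a uniform position. Alignment lengths and
#' percent identities are drawn uniformly from the given ranges (the
#' default alignment range 50-100 bp survives the >=50 bp filter; pass
#' e.g. `aln_len_range = c(30, 100)` for a sub-threshold mode). Rows are
#' shuffled before return, as an aligner's output order carries no meaning
#' here.
#'
#' @param markers data.frame from [generate_markers].
#' @param truth truth map from [apply_rearrangements].
#' @param drop_rate,spurious_rate rates in `[0, 1]`.
#' @param aln_len_range,pident_range uniform sampler bounds.
#' @param seed integer seed.
#' @return hit-table data.frame (`qseqid`, `sseqid`, `sstart` 1-based,
#'   `length`, `pident`) in the 5-column tabular dialect.
#' @export
emit_hits <- function(markers, truth, drop_rate = 0, spurious_rate = 0,
                      aln_len_range = c(50, 100), pident_range = c(90, 100),
                      seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(drop_rate >= 0, drop_rate <= 1,
            spurious_rate >= 0, spurious_rate <= 1)
  set.seed(substream_seed(seed, "hits"))
  marker_len <- attr(markers, "marker_len") %||% 100L
  n <- nrow(markers)
  if (n == 0L || drop_rate >= 1)
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      sstart = numeric(0), length = numeric(0),
                      pident = numeric(0), stringsAsFactors = FALSE))
  # map marker starts through the truth segments of their chromosome
  tpos <- numeric(n); tscf <- character(n)
  for (ch in unique(markers$query_chrom)) {
    sel <- which(markers$query_chrom == ch)
    seg <- truth[truth$q_chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$q_start), , drop = FALSE]
    idx <- findInterval(markers$start[sel], seg$q_start)
    stopifnot(all(idx >= 1))
    fwd <- seg$strand[idx] == "+"
    off <- markers$start[sel] - seg$q_start[idx]
    tp <- ifelse(fwd,
                 seg$t_start[idx] + off,
                 seg$t_start[idx] + (seg$q_end[idx] - markers$start[sel] -
                                       marker_len))
    tpos[sel] <- tp
    tscf[sel] <- seg$target_chrom[idx]
  }
  keep <- stats::runif(n) >= drop_rate
  qid <- markers$marker_id[keep]
  scf <- tscf[keep]; pos <- tpos[keep]
  m <- length(qid)
  scaffolds <- unique(truth$target_chrom)
  if (spurious_rate > 0 && length(scaffolds) > 1) {
    sp <- stats::runif(m) < spurious_rate
    if (any(sp)) {
      wrong <- vapply(scf[sp], function(s)
        sample(setdiff(scaffolds, s), 1L), "")
      tl <- vapply(wrong, function(s)
        max(truth$t_end[truth$target_chrom == s]), 0)
      scf[sp] <- wrong
      pos[sp] <- floor(stats::runif(sum(sp), 0, pmax(1, tl - marker_len)))
    }
  }
  pos <- pmax(pos, 0)
  hits <- data.frame(
    qseqid = qid, sseqid = scf, sstart = pos + 1,
    length = round(stats::runif(m, aln_len_range[1], aln_len_range[2])),
    pident = round(stats::runif(m, pident_range[1], pident_range[2]), 1),
    stringsAsFactors = FALSE)
  hits <- hits[sample.int(m), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write simulator interval annotations as GFF3
#' @param intervals interval data.frame (0-based half-open).
#' @param path output file.
#' @param source GFF3 source column.
#' @export
write_gff3 <- function(intervals, path, source = "synpaint") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(intervals)) {
    df <- data.frame(intervals$seq_id, source, intervals$kind,
                     intervals$start + 1, intervals$end, ".",
                     ifelse(intervals$strand %in% c("+", "-"),
                            intervals$strand, "."),
                     ".", paste0("ID=", intervals$kind,
                                 seq_len(nrow(intervals))))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write intervals as BED
#' @param intervals interval data.frame (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates 0-based half-open", con)
  if (nrow(intervals)) {
    df <- data.frame(intervals$seq_id, intervals$start, intervals$end,
                     intervals$attrs %||% ".")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a hit table in the 5-column tabular dialect
#' @param hits hit-table data.frame.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, c("qseqid", "sseqid", "sstart", "length",
                              "pident")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Hidden-fusion curation fixture
#'
#' Builds the scaffold set used to exercise breakpoint detection and
#' scaffold splitting: `n_macro` macrochromosome scaffolds, `n_micro`
#' microchromosome scaffolds of which one (`scf_fused`) is a concatenation
#' of two composition-distinct microchromosome segments, plus candidate
#' junctions (the true junction and `n_decoys` decoys).
#'
#' Unlike [simulate_query], whose per-window draws use the pooled class
#' distributions, this generator gives each scaffold (and each fused
#' segment) its own composition mean and draws windows around it at the
#' within-chromosome SD — the noise scale relevant for windows of a single
#' scaffold, where the pooled class SD would conflate between- and
#' within-chromosome variation. Decoy junctions are placed on a 0.5-Mb
#' grid at least `decoy_clearance` bp from the true junction, mirroring
#' the multi-megabase spacing of proximity-ligation sub-scaffold joins.
#'
#' @param seed integer seed.
#' @param n_macro,n_micro scaffold counts (`n_micro` includes the fused
#'   scaffold). Either may be 0 to generate only the other class.
#' @param macro_length,micro_length scaffold lengths in bp; the fused
#'   scaffold has length `2 * micro_length`.
#' @param gc_means GC% means of the two fused segments.
#' @param repeat_means repeat-fraction means of the two fused segments.
#' @param gene_mean genic-fraction mean (all windows).
#' @param window_sd named numeric: within-chromosome per-window SDs for
#'   `gc` (%), `rep` (repeat fraction) and `gene` (genic fraction).
#' @param n_decoys decoy junction count.
#' @param decoy_clearance minimum decoy distance from the true junction.
#' @param window_size window size in bp.
#' @return list: `assembly`, `genes`, `repeats`, `class_map`,
#'   `fused_scaffold`, `true_junction`, `candidates`.
#' @export
simulate_curation_fixture <- function(seed, n_macro = 6L, n_micro = 10L,
    macro_length = 2e7, micro_length = 8.5e6,
    gc_means = c(36.5, 40.5), repeat_means = c(0.45, 0.34),
    gene_mean = 0.27,
    window_sd = c(gc = 1.2, rep = 0.05, gene = 0.16),
    n_decoys = 10L, decoy_clearance = 3e6, window_size = 1e6) {
  if (missing(seed)) stop("seed is required")
  if (n_micro < 1) stop("need at least the fused micro scaffold")
  set.seed(substream_seed(seed, "curation_fixture"))
  cls <- composition_params()
  # scaffold plan: per scaffold a vector of per-window composition means
  plan <- list()
  if (n_macro > 0)
    for (i in seq_len(n_macro))
      plan[[paste0("scf_macro", i)]] <-
        list(len = macro_length, gc = cls$macro$gc_mean,
             rep = cls$macro$repeat_mean, class = "macro")
  plan[["scf_fused"]] <- list(len = 2 * micro_length, gc = gc_means,
                              rep = repeat_means, class = "micro")
  if (n_micro > 1)
    for (i in seq_len(n_micro - 1))
      plan[[paste0("scf_micro", i)]] <-
        list(len = micro_length, gc = cls$micro$gc_mean,
             rep = cls$micro$repeat_mean, class = "micro")
  seqs <- character(0)
  genes_l <- list(); reps_l <- list()
  for (nm in names(plan)) {
    pl <- plan[[nm]]
    # parameter windows break at the fusion junction so composition shifts
    # exactly where the two source scaffolds were joined
    bounds <- sort(unique(c(seq(0, pl$len, by = window_size), pl$len,
                            if (length(pl$gc) == 2) pl$len / 2)))
    ws <- bounds[-length(bounds)]; we <- bounds[-1]
    seg <- if (length(pl$gc) == 2) ifelse(we <= pl$len / 2, 1L, 2L)
           else rep(1L, length(ws))
    gc_w <- vapply(seq_along(ws), function(k)
      rtruncnorm(1, pl$gc[seg[k]], window_sd[["gc"]], 0, 100), 0)
    rep_w <- vapply(seq_along(ws), function(k)
      rtruncnorm(1, pl$rep[seg[k]], window_sd[["rep"]], 0, 1), 0)
    gd_w <- rtruncnorm(length(ws), gene_mean, window_sd[["gene"]], 0, 1)
    raws <- vector("list", length(ws))
    for (k in seq_along(ws))
      raws[[k]] <- random_window_bases(we[k] - ws[k], gc_w[k] / 100)
    seqs[nm] <- rawToChar(unlist(raws))
    for (k in seq_along(ws)) {
      iv <- place_in_window(ws[k], we[k], rep_w[k], 100, 5e3)
      if (length(iv$start))
        reps_l[[length(reps_l) + 1L]] <-
          data.frame(seq_id = nm, start = iv$start, end = iv$end,
                     strand = ".", kind = "repeat", attrs = ".",
                     stringsAsFactors = FALSE)
      iv <- place_in_window(ws[k], we[k], gd_w[k], 1e3, 5e4)
      if (length(iv$start))
        genes_l[[length(genes_l) + 1L]] <-
          data.frame(seq_id = nm, start = iv$start, end = iv$end,
                     strand = ".", kind = "gene", attrs = ".",
                     stringsAsFactors = FALSE)
    }
  }
  true_junction <- micro_length
  grid <- seq(window_size, 2 * micro_length - window_size, by = window_size / 2)
  grid <- grid[abs(grid - true_junction) >= decoy_clearance]
  decoys <- sort(sample(grid, min(n_decoys, length(grid))))
  genes <- do.call(rbind, genes_l); rownames(genes) <- NULL
  repeats <- do.call(rbind, reps_l); rownames(repeats) <- NULL
  list(assembly = assembly(seqs, name = "curation_fixture"),
       genes = genes, repeats = repeats,
       class_map = stats::setNames(vapply(plan, `[[`, "", "class"),
                                   names(plan)),
       fused_scaffold = "scf_fused",
       true_junction = true_junction,
       candidates = sort(c(true_junction, decoys)))
}
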