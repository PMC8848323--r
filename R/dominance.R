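# Simpson dominance of syntenic-block dispersion: for query chromosome i and
# target species j, p_ijk is the proportion of chromosome i's painted signal
# carried by target scaffold k; D_ij = sum_k p_ijk^2 and C_ij = 1/D_ij is the
# effective number of target chromosomes (SR).

#' Per-scaffold homology proportions from a painting
#'
#' For every (query chromosome, species) pair with at least one syntenic
#' block, block weight is aggregated per target scaffold and normalized to a
#' proportion vector p. Pairs without blocks are missing data (recorded in
#' the `missing` attribute), not zeros.
#'
#' @param painting a `painting` object (or its blocks data.frame).
#' @param weighting `"marker_count"` (default) weights scaffolds by markers
#'   inside blocks; `"base_span"` weights by query base span of blocks.
#' @return data.frame with columns `query_chrom`, `species`,
#'   `target_scaffold`, `weight`, `p`; attribute `missing` lists
#'   (query_chrom, species) pairs with no blocks.
#' @export
proportions_from_blocks <- function(painting,
                                    weighting = c("marker_count",
                                                  "base_span")) {
  weighting <- match.arg(weighting)
  b <- if (inherits(painting, "painting")) painting$blocks else painting
  w <- if (weighting == "marker_count") b$marker_count
       else b$query_end - b$query_start
  if (nrow(b) == 0L) {
    out <- data.frame(query_chrom = character(0), species = character(0),
                      target_scaffold = character(0), weight = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
    attr(out, "missing") <- data.frame(query_chrom = character(0),
                                       species = character(0))
    return(out)
  }
  agg <- stats::aggregate(w, by = list(query_chrom = b$query_chrom,
                                       species = b$species,
                                       target_scaffold = b$target_scaffold),
                          FUN = sum)
  names(agg)[4] <- "weight"
  tot <- stats::ave(agg$weight, agg$query_chrom, agg$species, FUN = sum)
  agg$p <- agg$weight / tot
  agg <- agg[order(agg$species, agg$query_chrom, -agg$weight,
                   agg$target_scaffold), , drop = FALSE]
  rownames(agg) <- NULL
  # missing pairs: chromosomes seen in the painting's marker set but absent
  # for some species
  miss <- data.frame(query_chrom = character(0), species = character(0))
  if (inherits(painting, "painting")) {
    chroms <- unique(painting$markers$query_chrom)
    sps <- painting$species
    grid <- expand.grid(query_chrom = chroms, species = sps,
                        stringsAsFactors = FALSE)
    have <- paste(agg$query_chrom, agg$species, sep = "\r")
    miss <- grid[!(paste(grid$query_chrom, grid$species, sep = "\r") %in%
                     have), , drop = FALSE]
    rownames(miss) <- NULL
  }
  attr(agg, "missing") <- miss
  agg
}

#' Simpson Dominance Index of a proportion vector
#'
#' `D = sum(p^2)` over the scaffold proportions of one (query chromosome,
#' species) pair. D ranges from 1/m (even spread over m scaffolds) to 1
#' (all homologies on a single scaffold).
#'
#' @param p numeric proportion vector; entries in (0, 1], summing to 1.
#' @param tol tolerance on `sum(p) == 1`.
#' @return D, dimensionless.
#' @examples
#' simpson_dominance(c(1))            # 1
#' simpson_dominance(rep(0.25, 4))    # 0.25
#' @export
simpson_dominance <- function(p, tol = 1e-9) {
  if (length(p) == 0L) stop("no homologies: empty proportion vector")
  if (any(p <= 0) || any(p > 1)) stop("proportions must lie in (0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  sum(p^2)
}

#' Effective number of target chromosomes
#'
#' The reciprocal of the Simpson Dominance Index: the number of equally
#' used target scaffolds that would produce the observed dominance. Ranges
#' from 1 (all signal on one scaffold) to m (even spread over m scaffolds).
#'
#' @param D Simpson dominance, in (0, 1].
#' @return C (the SR statistic), dimensionless.
#' @export
effective_chromosomes <- function(D) {
  if (any(D <= 0)) stop("D must be > 0")
  1 / D
}

#' Dominance analysis of a painting
#'
#' Computes per (query chromosome, species): m (number of target scaffolds
#' carrying blocks), D and C.
#'
#' @inheritParams proportions_from_blocks
#' @return data.frame of class `"dominance"` with columns `query_chrom`,
#'   `species`, `m`, `D`, `C`; attribute `missing` as in
#'   [proportions_from_blocks].
#' @export
dominance <- function(painting, weighting = c("marker_count", "base_span")) {
  pr <- proportions_from_blocks(painting, weighting)
  if (nrow(pr) == 0L) {
    out <- data.frame(query_chrom = character(0), species = character(0),
                      m = integer(0), D = numeric(0), C = numeric(0))
  } else {
    sp <- split(pr, paste(pr$species, pr$query_chrom, sep = "\r"))
    out <- do.call(rbind, lapply(sp, function(g) {
      D <- simpson_dominance(g$p)
      data.frame(query_chrom = g$query_chrom[1], species = g$species[1],
                 m = nrow(g), D = D, C = effective_chromosomes(D),
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$species, out$query_chrom), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "missing") <- attr(pr, "missing")
  class(out) <- c("dominance", "data.frame")
  out
}

#' Summarize dominance across species
#'
#' Per query chromosome, the mean and sample SD (n-1 denominator) of C over
#' the species with data; per species, the cumulative SR (sum of C over
#' query chromosomes with data). Missing (chromosome, species) pairs are
#' excluded and counted.
#'
#' @param results a `dominance` data.frame.
#' @return list of class `"dominance_summary"` with elements `per_chrom`
#'   (`query_chrom`, `mean_C`, `sd_C`, `n_species_with_data`),
#'   `per_species` (`species`, `cumulative_SR`, `n_chrom_with_data`), and
#'   `n_missing_pairs`.
#' @export
summarize_dominance <- function(results) {
  stopifnot(is.data.frame(results), all(c("query_chrom", "species", "C")
                                        %in% names(results)))
  per_chrom <- do.call(rbind, lapply(split(results, results$query_chrom),
    function(g) data.frame(query_chrom = g$query_chrom[1],
                           mean_C = mean(g$C),
                           sd_C = if (nrow(g) > 1) stats::sd(g$C) else NA_real_,
                           n_species_with_data = nrow(g),
                           stringsAsFactors = FALSE)))
  per_species <- do.call(rbind, lapply(split(results, results$species),
    function(g) data.frame(species = g$species[1],
                           cumulative_SR = sum(g$C),
                           n_chrom_with_data = nrow(g),
                           stringsAsFactors = FALSE)))
  rownames(per_chrom) <- rownames(per_species) <- NULL
  miss <- attr(results, "missing")
  structure(list(per_chrom = per_chrom, per_species = per_species,
                 n_missing_pairs = if (is.null(miss)) NA_integer_
                                   else nrow(miss)),
            class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat("Effective number of target chromosomes (SR), per query chromosome:\n")
  print(x$per_chrom, row.names = FALSE)
  cat("\nCumulative SR per species:\n")
  print(x$per_species, row.names = FALSE)
  if (!is.na(x$n_missing_pairs) && x$n_missing_pairs > 0)
    cat(sprintf("\n(%d chromosome x species pairs had no blocks and were excluded)\n",
                x$n_missing_pairs))
  invisible(x)
}

#' Write dominance tables as TSV
#' @param results a `dominance` data.frame.
#' @param path per-pair output file.
#' @export
write_dominance_tsv <- function(results, path) {
  write_tsv_with_header(as.data.frame(results), path,
                        "dominance per (query_chrom, species); C = 1/D")
}
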