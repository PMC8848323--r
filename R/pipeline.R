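# One-shot pipeline: simulate (optional) -> paint -> dominance ->
# composition -> karyotype, with a resolved config echoed to the output
# directory and a machine-readable run summary.

#' Read a pipeline run configuration
#'
#' YAML with the blocks accepted by [run_all]: either a `simulate` block
#' (karyotype counts/lengths, noise, rearrangement scenario) or explicit
#' `inputs` paths (`query_fasta`, `hits` as species->path map, `genes`,
#' `repeats`, `classes`), plus `painting` parameters (`marker_len`,
#' `min_aln_len`, `min_run`, `drop_n`), `window_size`, `seed`.
#'
#' @param path YAML file.
#' @return config list (validated by [run_all]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config validation: seed is required")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config validation: either a simulate block or an inputs block is required")
  if (!is.null(config$inputs)) {
    need <- c("query_fasta", "hits")
    for (f in need)
      if (is.null(config$inputs[[f]]))
        stop("config validation: inputs$", f, " is required")
    paths <- c(config$inputs$query_fasta, unlist(config$inputs$hits),
               config$inputs$genes, config$inputs$repeats)
    missing_p <- paths[!file.exists(paths)]
    if (length(missing_p))
      stop("config validation: missing input file(s): ",
           paste(missing_p, collapse = ", "))
  }
  invisible(TRUE)
}

#' A small bundled demo configuration
#'
#' Simulates a 5.2-Mb toy karyotype (2 macrochromosomes of 1 Mb, 4
#' microchromosomes of 0.3 Mb at a 100-kb parameter window), derives one
#' target species by fusing two micros and splitting one macro, and runs
#' the full pipeline. Completes in seconds.
#'
#' @param seed integer seed.
#' @return config list for [run_all].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = seed,
    window_size = 1e5,
    painting = list(marker_len = 100, min_aln_len = 50, min_run = 5,
                    drop_n = TRUE),
    simulate = list(
      n_macro = 2, n_micro = 4, macro_length = 1e6, micro_length = 3e5,
      param_window = 1e5,
      species = list(
        spA = list(ops = list(list(type = "fusion", a = "micro1",
                                   b = "micro2"),
                              list(type = "fission", a = "macro1",
                                   position = 5e5)),
                   drop_rate = 0.02, spurious_rate = 0.005),
        spB = list(ops = list(), drop_rate = 0, spurious_rate = 0))))
}

ops_from_config <- function(oplist) {
  lapply(oplist, function(o) {
    switch(o$type,
           fusion = fusion(o$a, o$b, o$orientation %||% "forward"),
           fission = fission(o$a, o$position),
           translocation = translocation(o$a, o$seg_start, o$seg_end, o$b,
                                         o$insert_pos),
           inversion = inversion(o$a, o$seg_start, o$seg_end),
           stop("unknown rearrangement op type: ", o$type))
  })
}

#' Run the full pipeline
#'
#' Executes simulate (if configured) -> paint -> dominance -> composition
#' and writes `painting.tsv`, `painting.bed`, `dominance.tsv`,
#' `dominance_per_chrom.tsv`, `dominance_per_species.tsv`, `track.tsv`,
#' `comparison.tsv`, a resolved `config.yaml` and `run_summary.json` to
#' `out_dir`. Any stage error aborts with the stage name; a
#' `RUN.partial` marker file is left behind on failure and removed on
#' success.
#'
#' @param config config list (see [read_run_config], [demo_config]).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the run summary as attribute `summary`.
#' @export
run_all <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(out_dir, "RUN.partial")
  file.create(partial)
  summary <- list(seed = config$seed, stages = list())
  stage <- "setup"
  result <- tryCatch({
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    pw <- config$painting %||% list()
    marker_len <- pw$marker_len %||% 100
    min_aln <- pw$min_aln_len %||% 50
    min_run <- pw$min_run %||% 5
    drop_n <- pw$drop_n %||% TRUE
    window_size <- config$window_size %||% 1e6

    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sb <- config$simulate
      spec <- karyotype_spec(sb$n_macro %||% 6, sb$n_micro %||% 11,
                             sb$macro_length %||% 2e7,
                             sb$micro_length %||% 8e6)
      sim <- simulate_query(spec, composition_params(), seed = config$seed,
                            window_size = sb$param_window %||% window_size)
      qasm <- sim$assembly; genes <- sim$genes; repeats <- sim$repeats
      class_map <- sim$class_map
      markers <- generate_markers(qasm, marker_len, drop_n)
      hit_tables <- list()
      for (sp in names(sb$species)) {
        spc <- sb$species[[sp]]
        tr <- apply_rearrangements(qasm, ops_from_config(spc$ops %||% list()))
        hit_tables[[sp]] <- emit_hits(
          markers, tr$truth, drop_rate = spc$drop_rate %||% 0,
          spurious_rate = spc$spurious_rate %||% 0,
          seed = substream_seed(config$seed, sp))
      }
      summary$stages$simulate <- list(n_chrom = length(qasm$seq),
                                      total_bp = total_length(qasm),
                                      n_species = length(hit_tables))
    } else {
      stage <- "load"
      qasm <- read_fasta(config$inputs$query_fasta)
      genes <- if (!is.null(config$inputs$genes))
        read_gff3_genes(config$inputs$genes) else NULL
      repeats <- if (!is.null(config$inputs$repeats))
        read_repeat_intervals(config$inputs$repeats,
                              config$inputs$repeat_format %||% "bed")
        else NULL
      class_map <- if (!is.null(config$inputs$classes)) {
        cl <- read_tsv_skip_comments(config$inputs$classes)
        stats::setNames(cl[[2]], cl[[1]])
      } else NULL
      hit_tables <- lapply(config$inputs$hits, read_hit_table)
    }

    stage <- "paint"
    p <- paint(qasm, hit_tables, marker_len = marker_len,
               min_aln_len = min_aln, min_run = min_run, drop_n = drop_n)
    write_painting_tsv(p, file.path(out_dir, "painting.tsv"))
    write_painting_bed(p, file.path(out_dir, "painting.bed"))
    summary$stages$paint <- list(n_markers = p$n_markers,
                                 n_blocks = nrow(p$blocks))

    stage <- "dominance"
    dom <- dominance(p)
    ds <- summarize_dominance(dom)
    write_dominance_tsv(dom, file.path(out_dir, "dominance.tsv"))
    write_tsv_with_header(ds$per_chrom,
                          file.path(out_dir, "dominance_per_chrom.tsv"),
                          "mean/SD of C (SR) per query chromosome across species")
    write_tsv_with_header(ds$per_species,
                          file.path(out_dir, "dominance_per_species.tsv"),
                          "cumulative SR per target species")
    summary$stages$dominance <- list(n_pairs = nrow(dom),
                                     n_missing_pairs = ds$n_missing_pairs)

    stage <- "composition"
    track <- build_track(qasm, genes, repeats, class_map,
                         window_size = window_size)
    write_track_tsv(track, file.path(out_dir, "track.tsv"))
    cmp <- NULL
    if (any(track$class == "macro") && any(track$class == "micro")) {
      cmp <- do.call(rbind, lapply(
        c("gene_frac", "gc_pct", "repeat_frac"), function(mt) {
          g <- compare_macro_micro(track, mt)
          data.frame(metric = mt, n_macro = g$n_macro, n_micro = g$n_micro,
                     mean_macro = g$mean_macro, mean_micro = g$mean_micro,
                     W_macro = g$W_macro, U = g$U, p_value = g$p_value,
                     stringsAsFactors = FALSE)
        }))
      write_tsv_with_header(cmp, file.path(out_dir, "comparison.tsv"),
                            "macro vs micro two-sided rank-sum tests")
    }
    summary$stages$composition <- list(n_windows = nrow(track))

    stage <- "finish"
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    file.remove(partial)
    out_dir
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(invisible(result), summary = summary)
}
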