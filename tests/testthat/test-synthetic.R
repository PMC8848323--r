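# Simulator determinism, rearrangement algebra and hit emission.

test_that("the generator is deterministic and its substreams are isolated", {
  spec <- karyotype_spec(1, 2, 1e5, 4e4)
  s1 <- simulate_query(spec, composition_params(), seed = 19,
                       window_size = 1e4)
  s2 <- simulate_query(spec, composition_params(), seed = 19,
                       window_size = 1e4)
  expect_identical(as.character(s1$assembly$seq), as.character(s2$assembly$seq))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$repeats, s2$repeats)
  s3 <- simulate_query(spec, composition_params(), seed = 20,
                       window_size = 1e4)
  expect_false(identical(as.character(s1$assembly$seq),
                         as.character(s3$assembly$seq)))
  # downstream hit emission does not perturb the genome stream
  tr <- apply_rearrangements(s1$assembly, list())
  mk <- generate_markers(s1$assembly)
  invisible(emit_hits(mk, tr$truth, seed = 99))
  s4 <- simulate_query(spec, composition_params(), seed = 19,
                       window_size = 1e4)
  expect_identical(as.character(s1$assembly$seq), as.character(s4$assembly$seq))
})

test_that("a zero-SD GC parameter yields windows at that GC within binomial noise", {
  params <- composition_params(
    macro = list(gc_mean = 50, gc_sd = 0, gene_mean = 0.1, gene_sd = 0,
                 repeat_mean = 0.1, repeat_sd = 0),
    micro = list(gc_mean = 50, gc_sd = 0, gene_mean = 0.1, gene_sd = 0,
                 repeat_mean = 0.1, repeat_sd = 0))
  sim <- simulate_query(karyotype_spec(1, 1, 1e5, 4e4), params, seed = 23,
                        window_size = 1e4)
  tr <- build_track(sim$assembly, class_map = sim$class_map,
                    window_size = 1e4)
  # 3.5-sigma binomial band for p = 0.5 at n = 1e4 is about +/- 1.75 points
  expect_true(all(abs(tr$gc_pct - 50) < 1.75))
})

test_that("infeasible per-window coverage requests error out", {
  params <- composition_params(
    macro = list(gc_mean = 40, gc_sd = 0, gene_mean = 0.999, gene_sd = 0,
                 repeat_mean = 0.1, repeat_sd = 0),
    micro = list(gc_mean = 40, gc_sd = 0, gene_mean = 0.999, gene_sd = 0,
                 repeat_mean = 0.1, repeat_sd = 0))
  expect_error(simulate_query(karyotype_spec(1, 0, 2e4, 1e4), params,
                              seed = 1, window_size = 1e4), "infeasible")
})

test_that("fusion and fission conserve bases and produce the expected maps", {
  a <- assembly(c(c1 = rand_seq(1000), c2 = rand_seq(600)), "q")
  fu <- apply_rearrangements(a, list(fusion("c1", "c2")))
  expect_equal(unname(seq_lengths(fu$assembly)), 1600)
  expect_equal(nrow(fu$truth), 2L)
  expect_equal(total_length(fu$assembly), total_length(a))
  expect_identical(as.character(fu$assembly$seq[[1]]),
                   paste0(as.character(a$seq[["c1"]]),
                          as.character(a$seq[["c2"]])))

  fi <- apply_rearrangements(a, list(fission("c1", 500)))
  expect_equal(sort(unname(seq_lengths(fi$assembly))),
               sort(c(500, 500, 600)))

  rf <- apply_rearrangements(a, list(fusion("c1", "c2",
                                            orientation = "reverse")))
  want <- paste0(as.character(a$seq[["c1"]]),
                 as.character(Biostrings::reverseComplement(a$seq[["c2"]])))
  expect_identical(as.character(rf$assembly$seq[[1]]), want)
})

test_that("an inversion applied twice restores the original sequence", {
  a <- assembly(c(c1 = rand_seq(1000)), "q")
  once <- apply_rearrangements(a, list(inversion("c1", 200, 700)))
  expect_false(identical(as.character(once$assembly$seq[[1]]),
                         as.character(a$seq[[1]])))
  twice <- apply_rearrangements(a, list(inversion("c1", 200, 700),
                                        inversion("c1", 200, 700)))
  expect_identical(as.character(twice$assembly$seq[[1]]),
                   as.character(a$seq[[1]]))
  # truth composes to the identity tiling
  tid <- twice$truth[order(twice$truth$q_start), ]
  expect_true(all(tid$strand == "+"))
  expect_equal(tid$q_start, tid$t_start)
})

test_that("translocations move segments between chromosomes exactly", {
  a <- assembly(c(c1 = rand_seq(1000), c2 = rand_seq(600)), "q")
  tl <- apply_rearrangements(a, list(translocation("c1", 100, 300, "c2",
                                                   250)))
  expect_equal(unname(seq_lengths(tl$assembly)[c("c1", "c2")]),
               c(800, 800))
  s1 <- as.character(a$seq[["c1"]]); s2 <- as.character(a$seq[["c2"]])
  expect_identical(as.character(tl$assembly$seq[["c2"]]),
                   paste0(substr(s2, 1, 250), substr(s1, 101, 300),
                          substr(s2, 251, 600)))
  expect_error(apply_rearrangements(a, list(fission("c1", 5000))),
               "outside")
  expect_error(apply_rearrangements(a, list(fusion("c1", "nope"))),
               "unknown chromosome")
})

test_that("hit emission respects drop and noise settings", {
  a <- assembly(c(c1 = rand_seq(5000), c2 = rand_seq(3000)), "q")
  tr <- apply_rearrangements(a, list())
  mk <- generate_markers(a)
  all_hits <- emit_hits(mk, tr$truth, seed = 37)
  expect_equal(nrow(all_hits), nrow(mk))
  expect_true(all(all_hits$length >= 50 & all_hits$length <= 100))
  # zero noise, identity map: every marker hits home at its own position
  m <- match(all_hits$qseqid, mk$marker_id)
  expect_identical(all_hits$sseqid, mk$query_chrom[m])
  expect_equal(all_hits$sstart, mk$start[m] + 1)

  none <- emit_hits(mk, tr$truth, drop_rate = 1, seed = 37)
  expect_equal(nrow(none), 0L)

  some <- emit_hits(mk, tr$truth, drop_rate = 0.5, seed = 37)
  expect_lt(nrow(some), nrow(mk))
})

test_that("sparse spurious hits do not assemble into blocks", {
  a <- assembly(c(c1 = rand_seq(20000), c2 = rand_seq(20000)), "q")
  tr <- apply_rearrangements(a, list())
  mk <- generate_markers(a)
  bad_block_runs <- 0L
  for (s in 1:10) {
    hits <- emit_hits(mk, tr$truth, spurious_rate = 0.01, seed = 100 + s)
    p <- paint(a, list(sp = hits))
    # any block on the wrong scaffold would come from chained spurious hits
    wrong <- sum(p$blocks$target_scaffold != p$blocks$query_chrom)
    if (wrong > 0) bad_block_runs <- bad_block_runs + 1L
  }
  expect_lte(bad_block_runs, 1L)
})

test_that("reverse-orientation fusions still paint to the fused scaffold", {
  sc <- tiny_scenario(43, n_macro = 1, n_micro = 2, macro_len = 4e5,
                      micro_len = 1e5)
  a <- sc$sim$assembly
  tr <- apply_rearrangements(a, list(fusion("micro1", "micro2", "reverse")))
  hits <- emit_hits(sc$markers, tr$truth, seed = 43)
  p <- paint(a, list(sp = hits))
  d <- dominance(p)
  expect_equal(d$C[d$query_chrom == "micro2"], 1)
  expect_equal(d$C[d$query_chrom == "micro1"], 1)
})
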