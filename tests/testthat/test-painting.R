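# Marker partitioning, best-hit filtering and syntenic-block chaining.

test_that("marker partition drops the trailing tile and N-containing tiles", {
  a <- assembly(c(chr1 = rand_seq(1050, gc = 0.5)), "t")
  mk <- generate_markers(a)
  expect_equal(nrow(mk), 10L)
  expect_equal(max(mk$end), 1000)

  s <- rand_seq(300)
  substr(s, 151, 151) <- "N"
  a <- assembly(c(chr1 = s), "t")
  mk <- generate_markers(a)
  expect_equal(mk$tile, c(0L, 2L))
  mk_kept <- generate_markers(a, drop_n = FALSE)
  expect_equal(mk_kept$tile, 0:2)
  expect_equal(mk_kept$contains_n, c(FALSE, TRUE, FALSE))

  # kept-rank index is gap-free even when tiles are dropped
  expect_equal(mk$index, 0:1)

  a <- assembly(c(tiny = "ACGT"), "t")
  expect_equal(nrow(generate_markers(a)), 0L)
})

test_that("marker ids are zero-padded and parse back, even with underscores", {
  a <- assembly(c(scaffold_12 = rand_seq(350)), "t")
  mk <- generate_markers(a)
  expect_equal(mk$marker_id, c("scaffold_12_000000", "scaffold_12_000001",
                               "scaffold_12_000002"))
  back <- parse_marker_id(mk$marker_id)
  expect_equal(back$query_chrom, rep("scaffold_12", 3))
  expect_equal(back$tile, 0:2)
  expect_error(parse_marker_id("nodigits"), "unparseable")
})

test_that("best-hit selection keeps one deterministic hit per marker", {
  a <- assembly(c(chr1 = rand_seq(1000)), "t")
  mk <- generate_markers(a)
  hits <- data.frame(
    qseqid = c("chr1_000000", "chr1_000000", "chr1_000001", "ghost_000001"),
    sseqid = c("sA", "sB", "sA", "sA"),
    sstart = c(1, 901, 101, 1), length = c(80, 95, 100, 100),
    pident = c(99, 95, 99, 99), stringsAsFactors = FALSE)
  best <- select_best_hits(hits, mk, "sp1")
  expect_equal(nrow(best), 2L)
  expect_equal(best$aln_length[best$tile == 0], 95)   # longer wins
  expect_equal(best$target_start[best$tile == 0], 900) # 0-based now
  expect_equal(attr(best, "n_unknown"), 1L)

  # invariant to row permutation
  set.seed(4)
  for (i in 1:5) {
    perm <- select_best_hits(hits[sample(nrow(hits)), ], mk, "sp1")
    attr(perm, "n_unknown") <- NULL
    ref <- best; attr(ref, "n_unknown") <- NULL
    expect_equal(perm, ref)
  }

  one_each <- hits[3, ]
  expect_equal(nrow(select_best_hits(one_each, mk, "sp1")), 1L)
})

test_that("alignment-length filter keeps >= 50 bp and preserves order", {
  r <- retained_frame(0:9, rep("sA", 10),
                      aln = c(49, 50, 51, 30, 100, 49, 50, 99, 10, 75))
  f <- filter_hits(r)
  expect_equal(f$tile, c(1, 2, 4, 6, 7, 9))
  expect_true(all(f$aln_length >= 50))
  expect_equal(nrow(filter_hits(r[0, ])), 0L)
  expect_equal(nrow(f), 6L)
})

test_that("chaining emits blocks only for runs of at least min_run markers", {
  b <- chain_markers(retained_frame(10:14, rep("A", 5)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$marker_count, 5L)
  expect_equal(b$first_index, 10L)
  expect_equal(b$query_start, 1000)
  expect_equal(b$query_end, 1500)

  expect_equal(nrow(chain_markers(retained_frame(10:13, rep("A", 4)))), 0L)

  b2 <- chain_markers(retained_frame(0:11, rep(c("A", "B"), c(5, 7))))
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$marker_count, c(5L, 7L))
  expect_equal(b2$target_scaffold, c("A", "B"))

  dup <- retained_frame(c(3, 3), c("A", "A"))
  expect_error(chain_markers(dup), "duplicate")
})

test_that("block emission threshold sweeps exactly with min_run", {
  r <- retained_frame(0:4, rep("A", 5))
  emitted <- vapply(1:10, function(mr) nrow(chain_markers(r, min_run = mr)),
                    0L)
  expect_equal(emitted > 0, 1:10 <= 5)
})

test_that("chaining equals a brute-force run-length oracle on random instances", {
  set.seed(99)
  for (i in 1:500) {
    n <- sample(1:40, 1)
    tiles <- sort(sample(0:60, n))
    scaffolds <- sample(LETTERS[1:3], n, replace = TRUE)
    min_run <- sample(1:6, 1)
    got <- chain_markers(retained_frame(tiles, scaffolds), min_run = min_run)
    want <- rle_blocks(tiles, scaffolds, min_run)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_index, want$first)
      expect_equal(got$last_index, want$last)
      expect_equal(got$marker_count, want$count)
      expect_equal(got$target_scaffold, as.character(want$scaffold))
    }
  }
})

test_that("strict collinear mode splits runs at target-direction changes", {
  ts <- c(0, 100, 200, 100, 0, 300, 400, 500, 600, 700) * 10
  r <- retained_frame(0:9, rep("A", 10), target_start = ts)
  loose <- chain_markers(r, min_run = 3)
  strict <- chain_markers(r, min_run = 3, require_collinear = TRUE)
  expect_equal(nrow(loose), 1L)
  expect_true(nrow(strict) > 1L)
  expect_lte(sum(strict$marker_count), sum(loose$marker_count))
  expect_true(all(strict$marker_count >= 3))
})

test_that("painting a noiseless unrearranged target gives one block per chromosome", {
  sim <- simulate_query(karyotype_spec(2, 2, 1e5, 4e4),
                        composition_params(), seed = 31, window_size = 1e4)
  tr <- apply_rearrangements(sim$assembly, list())
  mk <- generate_markers(sim$assembly)
  hits <- emit_hits(mk, tr$truth, seed = 31)
  p <- paint(sim$assembly, list(sp = hits))
  expect_equal(nrow(p$blocks), length(sim$assembly$seq))
  per_chrom <- split(p$blocks, p$blocks$query_chrom)
  for (ch in names(per_chrom)) {
    b <- per_chrom[[ch]]
    m <- mk[mk$query_chrom == ch, ]
    expect_equal(nrow(b), 1L)
    expect_equal(b$query_start, min(m$start))
    expect_equal(b$query_end, max(m$end))
    expect_equal(b$marker_count, nrow(m))
  }
})

test_that("painting reports retention stats and tolerates empty hit tables", {
  sim <- simulate_query(karyotype_spec(1, 1, 1e5, 4e4),
                        composition_params(), seed = 8, window_size = 1e4)
  tr <- apply_rearrangements(sim$assembly, list())
  mk <- generate_markers(sim$assembly)
  hits <- emit_hits(mk, tr$truth, seed = 8)
  empty <- hits[0, ]
  p <- paint(sim$assembly, list(spA = hits, spB = empty))
  expect_setequal(p$species, c("spA", "spB"))
  expect_equal(sum(p$blocks$species == "spB"), 0L)
  st <- p$stats
  # markers inside blocks <= retained <= raw hits, per species
  expect_true(all(st$n_markers_in_blocks <= st$n_retained))
  expect_true(all(st$n_retained <= st$n_raw_hits))
})

test_that("painting is invariant to hit-table row order", {
  sc <- tiny_scenario(13, n_macro = 1, n_micro = 2, macro_len = 2e5,
                      micro_len = 8e4)
  p1 <- paint(sc$sim$assembly, list(sp = sc$hits))
  set.seed(5)
  p2 <- paint(sc$sim$assembly, list(sp = sc$hits[sample(nrow(sc$hits)), ]))
  expect_equal(p1$blocks, p2$blocks)
})
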