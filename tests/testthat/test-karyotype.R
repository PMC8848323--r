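# Scaffold-to-chromosome assignment, length classes, breakpoint curation.

fab_track <- function(gc, rep_frac, gd, chrom = "scf", wlen = 1e6) {
  n <- length(gc)
  structure(data.frame(
    chrom = chrom, class = "micro", index = seq_len(n) - 1,
    start = (seq_len(n) - 1) * wlen, end = seq_len(n) * wlen,
    effective_len = wlen, gc_pct = gc, gene_frac = gd,
    repeat_frac = rep_frac), class = c("window_track", "data.frame"))
}

test_that("majority vote assigns scaffolds and flags ties", {
  a <- assembly(c(S = rand_seq(60e3), T2 = rand_seq(30e3)), "t")
  hits <- data.frame(
    qseqid = c(rep("m1", 8), rep("m2", 2), rep("m3", 5), rep("m4", 5)),
    sseqid = c(rep("S", 10), rep("T2", 10)),
    sstart = 1, length = 100, pident = 99)
  map <- c(m1 = "chr1", m2 = "chr9", m3 = "chr2", m4 = "chr3")
  asg <- assign_chromosomes(hits, map, a, macro_threshold = 50e3,
                            micro_min = 10e3)
  tab <- asg$table
  expect_equal(tab$source_label[tab$scaffold == "S"], "chr1")
  expect_equal(asg$evidence["S", "chr1"], 8)
  expect_true(tab$ambiguous[tab$scaffold == "T2"])  # 5 vs 5 tie
  expect_equal(tab$class[tab$scaffold == "S"], "macro")
  expect_equal(tab$chrom_label[tab$scaffold == "S"], "macro1")

  expect_error(assign_chromosomes(hits, c(zz = "chrZ"), a), "no assignable")
})

test_that("assignment is invariant to hit order and table duplication", {
  a <- assembly(c(S = rand_seq(5e3), T2 = rand_seq(3e3)), "t")
  hits <- data.frame(qseqid = c(rep("m1", 6), rep("m2", 4)),
                     sseqid = c(rep("S", 6), rep("T2", 4)),
                     sstart = 1, length = 100, pident = 99)
  map <- c(m1 = "chr1", m2 = "chr2")
  base <- assign_chromosomes(hits, map, a, macro_threshold = 4e3,
                             micro_min = 1e3)
  shuf <- assign_chromosomes(hits[sample(nrow(hits)), ], map, a,
                             macro_threshold = 4e3, micro_min = 1e3)
  dup <- assign_chromosomes(rbind(hits, hits), map, a,
                            macro_threshold = 4e3, micro_min = 1e3)
  expect_equal(shuf$table, base$table)
  expect_equal(dup$table$source_label, base$table$source_label)
  expect_equal(dup$table$chrom_label, base$table$chrom_label)
})

test_that("two labels sharing one majority scaffold raise a conflict", {
  a <- assembly(c(S = rand_seq(5e3)), "t")
  hits <- data.frame(qseqid = c(rep("m1", 5), rep("m2", 4)),
                     sseqid = "S", sstart = 1, length = 100, pident = 99)
  map <- c(m1 = "chr1", m2 = "chr2")
  expect_error(assign_chromosomes(hits, map, a, macro_threshold = 4e3),
               "conflict")
})

test_that("length classification uses inclusive macro and exclusive micro bounds", {
  lens <- c(a = 60e6, b = 30e6, c = 5e6, d = 50e6, e = 8e6)
  cl <- classify_macro_micro(lens)
  expect_equal(unname(cl), c("macro", "micro", "unplaced", "macro",
                             "unplaced"))
  expect_equal(length(classify_macro_micro(stats::setNames(numeric(0),
                                                           character(0)))),
               0L)
  expect_error(classify_macro_micro(c(a = -1)), "positive")
})

test_that("gap junctions are detected from long N runs only", {
  left <- rand_seq(2000); right <- rand_seq(2000)
  s <- paste0(left, strrep("N", 60), right)
  a <- assembly(c(scf = s, clean = rand_seq(500)), "t")
  j <- find_gap_junctions(a, "scf")
  expect_length(j, 1L)
  expect_true(j >= 2000 && j <= 2060)
  expect_length(find_gap_junctions(a, "clean"), 0L)
  short_gap <- assembly(c(scf = paste0(left, strrep("N", 10), right)), "t")
  expect_length(find_gap_junctions(short_gap, "scf"), 0L)
})

test_that("a composition shift at the true junction scores highest", {
  set.seed(83)
  gc <- c(rnorm(8, 36.5, 1.2), rnorm(8, 40.5, 1.2))
  rf <- c(rnorm(8, 0.45, 0.05), rnorm(8, 0.34, 0.05))
  gd <- rnorm(16, 0.27, 0.16)
  tr <- fab_track(gc, rf, gd)
  cands <- c(4e6, 8e6, 12e6)
  sc <- score_breakpoints("scf", cands, tr)
  expect_equal(sc$position[which.max(sc$shift_score)], 8e6)
  expect_false(any(sc$flagged))
})

test_that("homogeneous scaffolds yield no extreme shift z-scores", {
  set.seed(89)
  for (i in 1:50) {
    tr <- fab_track(rnorm(16, 38, 1.2), rnorm(16, 0.4, 0.05),
                    rnorm(16, 0.27, 0.16))
    sc <- score_breakpoints("scf", seq(4e6, 12e6, by = 1e6), tr)
    expect_true(all(abs(sc$z_gc) <= 3 & abs(sc$z_repeat) <= 3))
  }
})

test_that("candidates near the scaffold edge are flagged but scored", {
  set.seed(97)
  tr <- fab_track(rnorm(6, 38, 1), rnorm(6, 0.4, 0.05), rnorm(6, 0.27, 0.1))
  sc <- score_breakpoints("scf", c(5e5, 3e6), tr)
  expect_true(sc$flagged[1])   # < 1 whole window on the left
  expect_false(is.na(sc$shift_score[2]))
})

test_that("splitting picks the lowest-GD passer and conserves the sequence", {
  s <- rand_seq(4000)
  a <- assembly(c(scf = s, other = rand_seq(1000)), "t")
  scored <- data.frame(scaffold = "scf", position = c(1000, 2500, 3000),
                       delta_gc = c(4, 4, 0.1), delta_repeat = c(0.1, 0.1, 0),
                       local_gd = c(0.25, 0.10, 0.05),
                       z_gc = c(1.5, 1.5, -1), z_repeat = c(1.5, 1.5, -1),
                       shift_score = c(3, 3, -2), flagged = FALSE,
                       chosen = FALSE)
  res <- split_scaffold(a, "scf", scored)
  expect_equal(res$report$position, 2500)   # min local_gd among passers
  expect_setequal(names(res$assembly$seq), c("scf_L", "scf_R", "other"))
  expect_equal(total_length(res$assembly), total_length(a))
  glued <- paste0(as.character(res$assembly$seq[["scf_L"]]),
                  as.character(res$assembly$seq[["scf_R"]]))
  expect_identical(glued, s)

  scored$shift_score <- -1
  expect_error(split_scaffold(a, "scf", scored), "no supported breakpoint")
})

test_that("the hidden-fusion fixture is curated to the expected karyotype", {
  fx <- simulate_curation_fixture(seed = 7, n_macro = 2, n_micro = 4,
                                  macro_length = 6e6, micro_length = 2e6,
                                  window_size = 5e5, decoy_clearance = 1.2e6,
                                  n_decoys = 4)
  track <- build_track(fx$assembly, fx$genes, fx$repeats, fx$class_map,
                       window_size = 5e5)
  sc <- score_breakpoints(fx$fused_scaffold, fx$candidates, track)
  res <- split_scaffold(fx$assembly, fx$fused_scaffold, sc)
  cl <- classify_macro_micro(seq_lengths(res$assembly),
                             macro_threshold = 5e6, micro_min = 1e6)
  expect_equal(sum(cl == "micro"), 5L)  # 3 intact + the 2 split halves
  expect_equal(sum(cl == "macro"), 2L)
  expect_equal(res$report$position, fx$true_junction)
})
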