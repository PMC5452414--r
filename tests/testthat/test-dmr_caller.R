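# minimal hand-built CX records for arithmetic-level checks
cx_row <- function(pos, meth, unmeth, context = "CHH", chrom = "chr1",
                   strand = "+") {
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         context = context, meth = meth, unmeth = unmeth)
}
toy_genome <- genome_from_seqs(c(chr1 = paste(rep("A", 1000),
                                              collapse = "")))

test_that("bin pooling arithmetic and the coverage rule", {
  wt <- rbind(cx_row(10, 3, 7), cx_row(20, 2, 8))
  mut <- rbind(cx_row(10, 1, 9), cx_row(20, 0, 10))
  bins <- bin_methylation(wt, mut, toy_genome)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$level_wt, 5 / 20)
  expect_equal(bins$n_sites, 2L)

  # a site covered 3x in WT is not informative ("covered at least four
  # times" in BOTH samples); the lone-site bin becomes untestable
  wt2 <- cx_row(10, 1, 2)
  mut2 <- cx_row(10, 5, 5)
  expect_equal(nrow(bin_methylation(wt2, mut2, toy_genome)), 0L)

  # contexts split into separate bins
  wt3 <- rbind(cx_row(10, 3, 7, "CG"), cx_row(20, 3, 7, "CHH"))
  mut3 <- rbind(cx_row(10, 3, 7, "CG"), cx_row(20, 3, 7, "CHH"))
  b3 <- bin_methylation(wt3, mut3, toy_genome)
  expect_equal(sort(b3$context), c("CG", "CHH"))

  # pooled total-context mode collapses them
  b4 <- bin_methylation(wt3, mut3, toy_genome, pool_contexts = TRUE)
  expect_equal(b4$context, "total")
  expect_equal(b4$n_sites, 2L)
})

test_that("significance needs BOTH the level difference and the q cutoff", {
  mk <- function(meth_wt, unmeth_wt, meth_mut, unmeth_mut,
                 context = "CHH") {
    wt <- cx_row(10, meth_wt, unmeth_wt, context)
    mut <- cx_row(10, meth_mut, unmeth_mut, context)
    test_bins(bin_methylation(wt, mut, toy_genome))
  }
  # CHH diff 0.25 with a strong p -> significant
  sig <- mk(30, 70, 5, 95)
  expect_true(sig$significant)
  expect_equal(sig$direction, "hypo")
  expect_equal(sig$p, fisher_exact_2x2(30, 70, 5, 95))

  # tiny p but diff 0.08 < 0.1 threshold -> not significant
  ns <- mk(800, 9200, 0, 10000)
  expect_lt(ns$p, 1e-10)
  expect_lt(abs(ns$diff_level), 0.1)
  expect_false(ns$significant)

  # CG diff 0.35 < 0.4 threshold -> not significant
  cg <- mk(7000, 3000, 3500, 6500, context = "CG")
  expect_equal(cg$diff_level, -0.35, tolerance = 1e-9)
  expect_false(cg$significant)
})

test_that("bins join across gaps of at most 200 bp, never across direction", {
  sig <- data.table::data.table(
    chrom = "chr1", start = c(1000L, 1200L), end = c(1100L, 1300L),
    context = "CHH", diff_level = c(-0.3, -0.25), q = c(1e-4, 1e-3),
    significant = TRUE, direction = "hypo")
  d1 <- call_dmrs(sig, join_gap = 200L)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$start, 1000L)
  expect_equal(d1$end, 1300L)
  expect_equal(d1$n_bins, 2L)
  expect_equal(d1$min_q, 1e-4)

  sig2 <- data.table::copy(sig)[2, start := 1400L][2, end := 1500L]
  expect_equal(nrow(call_dmrs(sig2, join_gap = 200L)), 2L)
  # gap exactly 200 joins; a smaller join_gap splits it
  sig3 <- data.table::copy(sig)[2, `:=`(start = 1300L, end = 1400L)]
  expect_equal(nrow(call_dmrs(sig3, join_gap = 200L)), 1L)
  expect_equal(nrow(call_dmrs(sig3, join_gap = 199L)), 2L)

  # adjacent hypo and hyper bins never merge
  sig4 <- data.table::copy(sig)[2, `:=`(diff_level = 0.3,
                                        direction = "hyper")]
  d4 <- call_dmrs(sig4)
  expect_equal(nrow(d4), 2L)
  expect_setequal(d4$direction, c("hypo", "hyper"))
})

test_that("joining matches the brute-force transitive-closure oracle", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(1:15, 1)
    starts <- sort(sample(seq(0, 5000, by = 100), n)) # bin starts
    bins <- data.table::data.table(
      chrom = "chr1", start = starts, end = starts + 100L,
      context = "CHH", diff_level = -0.3, q = 1e-4,
      significant = TRUE, direction = "hypo")
    gap <- sample(c(0L, 100L, 200L, 300L), 1)
    got <- call_dmrs(bins, join_gap = gap)
    want <- oracle_merge_bins(bins$start, bins$end, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("DMR calls are monotone in the cutoffs and never self-overlap", {
  sim <- tiny_sim()
  wt <- simulate_methylome(sim, "WT", seed = 61)
  pkl <- simulate_methylome(sim, "pkl", seed = 62)
  bins <- bin_methylation(wt, pkl, sim$genome)
  strict <- test_bins(bins, q_cutoff = 0.01)
  loose <- test_bins(bins, q_cutoff = 0.05)
  expect_true(all(strict[significant == TRUE, paste(chrom, context, start)]
                  %in% loose[significant == TRUE,
                             paste(chrom, context, start)]))
  high_thr <- test_bins(bins, thresholds = c(CG = 0.5, CHG = 0.3,
                                             CHH = 0.2, total = 0.2))
  expect_true(all(high_thr[significant == TRUE,
                           paste(chrom, context, start)]
                  %in% loose[significant == TRUE,
                             paste(chrom, context, start)]))

  dmrs <- call_dmrs(loose)
  expect_gt(nrow(dmrs), 0)
  by_set <- split(dmrs, paste(dmrs$context, dmrs$direction))
  for (s in by_set) {
    data.table::setorder(s, chrom, start)
    if (nrow(s) > 1)
      expect_true(all(s[, start - data.table::shift(end, fill = -1L),
                        by = chrom]$V1 > 0))
  }
  # q >= p on every tested bin
  expect_true(all(loose$q >= loose$p - 1e-15))
})

test_that("dmr_stats sums and averages lengths", {
  d <- data.table::data.table(chrom = "chr1", start = c(0L, 1000L),
                              end = c(100L, 1300L))
  st <- dmr_stats(d)
  expect_equal(st$n, 2L)
  expect_equal(st$mean_length, 200)
  expect_equal(st$total_length_bp, 400)
  expect_equal(dmr_stats(d[0]), list(n = 0L, mean_length = 0,
                                     total_length_bp = 0))
  expect_equal(dmr_stats(d[2][, end := 1315L])$mean_length, 315)
})
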