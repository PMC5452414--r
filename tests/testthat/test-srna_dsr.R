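toy_genome2 <- genome_from_seqs(c(chr1 = paste(rep("A", 1000),
                                               collapse = "")))
mk_reads <- function(...) data.table::rbindlist(list(...))
rd <- function(start, len = 24L, strand = "+", multi = FALSE,
               chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = start,
                         end = start + len, strand = strand,
                         length_nt = len, multi = multi)
}

test_that("read filtering: mask, size window, multimappers, totals", {
  mask <- data.table::data.table(chrom = "chr1", start = 500L, end = 600L)
  reads <- mk_reads(rd(100), rd(550),            # second inside mask
                    rd(200, len = 21L),          # counts to total only
                    rd(300, len = 35L),          # outside 18-30
                    rd(400, multi = TRUE))       # multimapper
  f <- filter_srna_reads(reads, structural_mask = mask)
  expect_equal(f$total_mapped, 2L)               # 24nt@100 + 21nt@200
  bins <- bin_and_normalize(f, toy_genome2)
  expect_equal(sum(bins$count), 1L)              # only the 24-nt read
  expect_equal(bins[start == 100L, count], 1L)
  expect_error(filter_srna_reads(reads[, !"length_nt"]), "length_nt")
})

test_that("binning uses the 5' end and RPTM arithmetic is exact", {
  # plus read with 5' end 199 -> bin [100,200); minus read spanning a
  # boundary with 5' end at its last base
  reads <- mk_reads(rd(199), rd(180, strand = "-"))  # minus 5' end = 203
  f <- filter_srna_reads(reads)
  bins <- bin_and_normalize(f, toy_genome2)
  expect_equal(bins[start == 100L, count], 1L)
  expect_equal(bins[start == 200L, count], 1L)

  b <- srna_bins(data.table::data.table(chrom = "chr1", start = 0L,
                                        end = 100L, count = 12L),
                 total_mapped = 6e6)
  expect_equal(b$rptm, 20)
  expect_error(srna_bins(b[, .(chrom, start, end, count)], 0),
               "positive")
})

test_that("RPTM and p-values are invariant under joint count scaling", {
  counts <- data.table::data.table(chrom = "chr1",
                                   start = seq(0L, 900L, 100L),
                                   end = seq(100L, 1000L, 100L),
                                   count = c(0L, 5L, 50L, 200L, 3L, 0L,
                                             120L, 80L, 10L, 60L))
  a1 <- srna_bins(counts, 1e5)
  a2 <- srna_bins(data.table::copy(counts)[, count := count * 3L], 3e5)
  expect_equal(a1$rptm, a2$rptm)
  m1 <- srna_bins(data.table::copy(counts)[, count := rev(count)], 1e5)
  m2 <- srna_bins(data.table::copy(counts)[, count := rev(count) * 3L],
                  3e5)
  d1 <- call_dsrs(a1, m1, min_rptm = 0)
  d2 <- call_dsrs(a2, m2, min_rptm = 0)
  # scaling counts and totals by k leaves RPTM unchanged exactly; the
  # exact test sharpens with depth but preserves the evidence ordering
  expect_equal(d1$bins$rptm_wt, d2$bins$rptm_wt)
  expect_equal(d1$bins$rptm_mut, d2$bins$rptm_mut)
  expect_gte(stats::cor(log(d1$bins$p), log(d2$bins$p),
                        method = "spearman"), 0.99)
})

test_that("the RPTM > 5 retention filter is strict and DSRs behave", {
  # bin at RPTM exactly 5.0 in one sample, 4.0 in the other -> dropped
  wt <- srna_bins(data.table::data.table(chrom = "chr1", start = 0L,
                                         end = 100L, count = 5L), 1e7)
  mut <- srna_bins(data.table::data.table(chrom = "chr1", start = 0L,
                                          end = 100L, count = 4L), 1e7)
  expect_equal(nrow(call_dsrs(wt, mut)$bins), 0L)

  # 100 vs 0 at equal totals: down-DSR with p = 2 * 0.5^100
  wt2 <- srna_bins(data.table::data.table(chrom = "chr1", start = 0L,
                                          end = 100L, count = 100L), 1e6)
  mut2 <- srna_bins(data.table::data.table(chrom = "chr1", start = 0L,
                                           end = 100L, count = 0L), 1e6)
  res <- call_dsrs(wt2, mut2)
  expect_equal(nrow(res$dsrs), 1L)
  expect_equal(res$dsrs$direction, "down")
  expect_equal(res$dsrs$p, 2 * 0.5^100, tolerance = 1e-12)

  # equal counts and totals: p = 1, never a DSR
  eq <- call_dsrs(wt2, wt2)
  expect_equal(eq$bins$p, 1)
  expect_equal(nrow(eq$dsrs), 0L)

  # adjacent significant same-direction bins merge (gap 0 only)
  cnt <- function(x) srna_bins(
    data.table::data.table(chrom = "chr1",
                           start = c(0L, 100L, 300L),
                           end = c(100L, 200L, 400L), count = x), 1e6)
  res2 <- call_dsrs(cnt(c(200L, 150L, 180L)), cnt(c(0L, 0L, 0L)))
  expect_equal(nrow(res2$dsrs), 2L)
  expect_equal(res2$dsrs$start, c(0L, 300L))
  expect_equal(res2$dsrs$end, c(200L, 400L))
})

test_that("the DSR test holds its FDR under a null simulation", {
  set.seed(77)
  n_bins <- 10000
  mu <- 60
  counts <- function() data.table::data.table(
    chrom = "chr1", start = seq(0L, by = 100L, length.out = n_bins),
    end = seq(100L, by = 100L, length.out = n_bins),
    count = rpois(n_bins, mu))
  a <- srna_bins(counts(), n_bins * mu)
  b <- srna_bins(counts(), n_bins * mu)
  res <- call_dsrs(a, b, min_rptm = 5, fdr = 0.01)
  frac_sig <- mean(res$bins$q < 0.01)
  expect_lte(frac_sig, 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(res$bins)))
})

test_that("call_degs applies both the FDR and the fold cutoff", {
  cnt <- data.table::data.table(
    id = c("up1", "flat", "weak", "zero"),
    kind = c("TE", "gene", "gene", "gene"),
    count_wt = c(10L, 5000L, 40000L, 0L),
    count_mut = c(100L, 5000L, 60000L, 0L))
  res <- call_degs(cnt)
  expect_equal(res[id == "up1", status], "up")
  expect_gt(res[id == "up1", fold_change], 2)
  expect_equal(res[id == "flat", status], "ns")
  # fold 1.5 with a tiny p is still ns
  expect_lt(res[id == "weak", p], 1e-6)
  expect_equal(res[id == "weak", status], "ns")
  # zero-total features are untested
  expect_true(is.na(res[id == "zero", status]))
  expect_true(is.na(res[id == "zero", p]))
})

test_that("delta_scatter pools regions and reports coupled correlations", {
  sim <- tiny_sim()
  wtl <- simulate_srna_library(sim, "WT", library_size = 2e5, seed = 81)
  wtb <- srna_bins(wtl$bins, wtl$total_mapped)
  cx <- simulate_methylome(sim, "WT", seed = 82)
  regions <- sim$truth$loci[class == "RdDM", .(chrom, start, end)]

  # identical samples: all deltas 0, correlations undefined (NA)
  ds <- delta_scatter(regions, wtb, wtb, cx, cx)
  expect_true(all(abs(ds$table$dlog_rptm) < 1e-12))
  expect_true(all(abs(ds$table$dlevel_CHH) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(ds$correlations$estimate)))

  # construct a monotone coupling: per-locus siRNA fold tied to the CHH
  # drop -> strong positive Spearman
  set.seed(83)
  # restrict to loci with a high WT CHH baseline so the planted drop is
  # never clipped at zero methylation
  loci <- sim$truth$loci[subclass == "pkl_hypo", .(chrom, start, end)]
  drop <- seq(0.02, 0.30, length.out = nrow(loci))
  cx_mut <- data.table::copy(cx)
  bins_mut <- data.table::copy(wtb)
  for (i in seq_len(nrow(loci))) {
    sel <- cx_mut$chrom == loci$chrom[i] & cx_mut$pos >= loci$start[i] &
      cx_mut$pos < loci$end[i] & cx_mut$context == "CHH"
    tot <- cx_mut$meth[sel] + cx_mut$unmeth[sel]
    wt_lv <- sum(cx$meth[sel]) / sum(tot)
    newm <- rbinom(sum(sel), tot, max(0.005, wt_lv - drop[i]))
    cx_mut$meth[sel] <- newm
    cx_mut$unmeth[sel] <- tot - newm
    bsel <- bins_mut$chrom == loci$chrom[i] &
      bins_mut$start < loci$end[i] & bins_mut$end > loci$start[i]
    bins_mut$count[bsel] <-
      as.integer(round(bins_mut$count[bsel] * (1 - drop[i] * 2.5)))
  }
  bins_mut <- srna_bins(bins_mut[, .(chrom, start, end, count)],
                        attr(wtb, "total_mapped"))
  ds2 <- delta_scatter(loci, wtb, bins_mut, cx, cx_mut)
  sp <- ds2$correlations[context == "CHH" & method == "spearman",
                         estimate]
  expect_gt(sp, 0.9)

  # anti-coupled construction flips the sign
  ds3 <- delta_scatter(loci, bins_mut, wtb, cx, cx_mut)
  sp3 <- ds3$correlations[context == "CHH" & method == "spearman",
                          estimate]
  expect_lt(sp3, -0.9)
})
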