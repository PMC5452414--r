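toy_genome3 <- genome_from_seqs(c(chr1 = paste(rep("A", 200),
                                               collapse = "")))

test_that("build_partition reproduces the worked example and tiles the genome", {
  feats <- data.table::data.table(
    chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L),
    kind = c("gene", "TE"))
  part <- build_partition(feats, toy_genome3)
  expect_equal(part[class == "gene", .(start, end)],
               data.table::data.table(start = 0L, end = 50L))
  expect_equal(part[class == "gene/TE", .(start, end)],
               data.table::data.table(start = 50L, end = 100L))
  expect_equal(part[class == "TE", .(start, end)],
               data.table::data.table(start = 100L, end = 150L))
  expect_equal(part[class == "intergenic", .(start, end)],
               data.table::data.table(start = 150L, end = 200L))
  expect_equal(sum(part$end - part$start), 200L)

  # no features -> all intergenic; identical gene and TE -> all gene/TE
  p0 <- build_partition(feats[0], toy_genome3)
  expect_equal(p0$class, "intergenic")
  p1 <- build_partition(data.table::data.table(
    chrom = "chr1", start = c(0L, 0L), end = c(200L, 200L),
    kind = c("gene", "TE")), toy_genome3)
  expect_equal(p1$class, "gene/TE")
  expect_error(build_partition(data.table::data.table(
    chrom = "chr1", start = 0L, end = 500L, kind = "gene"), toy_genome3),
    "beyond")
})

test_that("partition matches the per-bp bitmap oracle on random inputs", {
  set.seed(91)
  L <- 2000L
  g <- genome_from_seqs(c(chr1 = paste(rep("A", L), collapse = "")))
  for (i in 1:40) {
    genes <- rand_regions(sample(1:8, 1), L, 200L)
    tes <- rand_regions(sample(1:8, 1), L, 200L)
    feats <- rbind(data.table::copy(genes)[, kind := "gene"],
                   data.table::copy(tes)[, kind := "TE"])
    part <- build_partition(feats, g)
    got <- sapply(c("gene", "TE", "gene/TE", "intergenic"), function(cl)
      part[class == cl, sum(end - start)])
    want <- bitmap_partition(genes, tes, L)
    expect_equal(unname(got), unname(want))
    expect_equal(sum(got), L)  # exact tiling
  }
})

test_that("distribute_regions is bp-weighted and conserving", {
  feats <- data.table::data.table(chrom = "chr1", start = 0L, end = 100L,
                                  kind = "TE")
  part <- build_partition(feats, toy_genome3)
  fr <- distribute_regions(data.table::data.table(
    chrom = "chr1", start = 20L, end = 60L), part)
  expect_equal(fr[["TE"]], 1)
  fr2 <- distribute_regions(data.table::data.table(
    chrom = "chr1", start = 50L, end = 150L), part)
  expect_equal(fr2[["TE"]], 0.5)
  expect_equal(fr2[["intergenic"]], 0.5)
  expect_equal(sum(fr2), 1, tolerance = 1e-9)
  fr3 <- distribute_regions(data.table::data.table(
    chrom = character(), start = integer(), end = integer()), part)
  expect_equal(sum(fr3), 0)
  expect_equal(attr(fr3, "n"), 0L)
})

test_that("overlap_sets counts, bp and jaccard match the examples and oracle", {
  a <- data.table::data.table(chrom = "chr1", start = 0L, end = 100L)
  b <- data.table::data.table(chrom = "chr1", start = 50L, end = 150L)
  ov <- overlap_sets(a, b)
  expect_equal(ov$n_a_overlapping_b, 1L)
  expect_equal(ov$overlap_bp, 50)
  expect_equal(ov$jaccard_bp, 50 / 150)

  far <- data.table::data.table(chrom = "chr1", start = 180L, end = 190L)
  ov2 <- overlap_sets(a, far)
  expect_equal(ov2$n_a_overlapping_b, 0L)
  expect_equal(ov2$overlap_bp, 0)

  inner <- data.table::data.table(chrom = "chr1", start = 10L, end = 20L)
  ov3 <- overlap_sets(inner, a)
  expect_equal(ov3$overlap_bp, ov3$total_bp_a)

  # min_bp threshold
  expect_equal(overlap_sets(a, b, min_bp = 51L)$n_a_overlapping_b, 0L)

  set.seed(92)
  L <- 2000L
  for (i in 1:40) {
    x <- rand_regions(sample(1:10, 1), L)
    y <- rand_regions(sample(1:10, 1), L)
    ov <- overlap_sets(x, y)
    expect_equal(ov$overlap_bp, bitmap_overlap_bp(x, y, L))
    expect_equal(ov$overlap_bp, overlap_sets(y, x)$overlap_bp)
    expect_gte(ov$jaccard_bp, 0)
    expect_lte(ov$jaccard_bp, 1)
  }
})

test_that("percent_overlap rounds half-up at the reported precision", {
  expect_equal(percent_overlap(6117, 6670), 91.7)
  expect_equal(percent_overlap(3608, 6394), 56.4)
  expect_equal(percent_overlap(0, 10), 0)
  expect_equal(percent_overlap(1, 16), 6.3)  # 6.25 rounds up
  expect_error(percent_overlap(1, 0), "positive")
})

test_that("flank_associate reports pairs and distinct counts", {
  feats <- data.table::data.table(chrom = "chr1", start = 5000L,
                                  end = 6000L, id = "g1")
  near <- data.table::data.table(chrom = "chr1", start = 4400L,
                                 end = 4500L)  # 500 bp upstream
  far <- data.table::data.table(chrom = "chr1", start = 2000L,
                                end = 3500L)   # 1500 bp away
  expect_equal(flank_associate(feats, near)$n_pairs, 1L)
  expect_equal(flank_associate(feats, far)$n_pairs, 0L)

  two <- data.table::data.table(chrom = "chr1",
                                start = c(5000L, 8000L),
                                end = c(6000L, 9000L),
                                id = c("g1", "g2"))
  spanning <- data.table::data.table(chrom = "chr1", start = 6500L,
                                     end = 7500L)
  fa <- flank_associate(two, spanning)
  expect_equal(fa$n_pairs, 2L)
  expect_equal(fa$n_dmrs, 1L)
  expect_equal(fa$n_features, 2L)
})

test_that("promoter_methylation is strand-aware", {
  cx <- data.table::data.table(
    chrom = "chr1",
    pos = c(4500L, 6500L),
    strand = "+", context = "CHH",
    meth = c(8L, 1L), unmeth = c(2L, 9L))
  feats <- data.table::data.table(chrom = "chr1", start = 5000L,
                                  end = 6000L, strand = c("+"),
                                  id = "g1")
  pm <- promoter_methylation(feats, list(s1 = cx))
  expect_equal(pm[context == "CHH", level], 0.8)  # promoter [4000,5000)
  feats$strand <- "-"
  pm2 <- promoter_methylation(feats, list(s1 = cx))
  expect_equal(pm2[context == "CHH", level], 0.1) # promoter [6000,7000)
  expect_equal(pm2[context == "CG", n_sites], 0L)
  expect_true(is.na(pm2[context == "CG", level]))
  feats$strand <- "."
  expect_error(promoter_methylation(feats, list(s1 = cx)), "strand")
})

test_that("state_enrichment: null fold 1, containment fold, closed-form p", {
  L <- 100000L
  g <- genome_from_seqs(c(chr1 = paste(rep("A", 100), collapse = "")))
  g$index$length <- L  # big coordinate frame without a big string
  states <- data.table::data.table(
    chrom = "chr1", start = seq(0L, L - 10000L, 10000L),
    end = seq(10000L, L, 10000L), state = rep(1:9, length.out = 10))

  # the whole genome against any state has fold exactly 1
  whole <- data.table::data.table(chrom = "chr1", start = 0L, end = L)
  enr <- state_enrichment(whole, states, g)
  expect_equal(enr$fold[!is.na(enr$fold)],
               rep(1, sum(!is.na(enr$fold))))

  # all region bp inside a state occupying 10% of the genome -> fold 10
  # and the binomial upper tail at 100/100 units is 0.1^100
  inside <- data.table::data.table(chrom = "chr1", start = 10000L,
                                   end = 20000L)  # state 2 exactly
  enr2 <- state_enrichment(inside, states, g)
  expect_equal(enr2[state == 2, fold], 10)
  expect_equal(log10(enr2[state == 2, p]), 100 * log10(0.1),
               tolerance = 0.02)

  # uniformly drawn regions: no state strongly enriched
  set.seed(93)
  st <- sample.int(L - 200L, 300L) - 1L
  unif <- data.table::data.table(chrom = "chr1", start = st,
                                 end = st + 100L)
  enr3 <- state_enrichment(unif, states, g)
  expect_true(all(enr3$q > 0.05, na.rm = TRUE))

  # permutation mode agrees qualitatively with the binomial mode
  enr4 <- state_enrichment(inside, states, g, method = "permutation",
                           n_perm = 200, seed = 4)
  expect_lt(enr4[state == 2, p], 0.01)
})
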