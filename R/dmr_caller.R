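#' Pool per-cytosine counts into 100-bp methylation bins
#'
#' The genome is divided into fixed-width bins and, separately for each
#' cytosine context, counts are pooled over the informative cytosines of
#' the bin. A cytosine is informative iff its coverage is at least
#' `min_cov` in BOTH samples ("covered at least four times" applied per
#' site, per sample). Bins with fewer than `min_sites` informative
#' cytosines are untestable and dropped. Terminal short bins at chromosome
#' ends are retained.
#'
#' @param wt,mut CX-style data.tables (chrom, pos, strand, context, meth,
#'   unmeth) for the two samples, on the same genome.
#' @param genome `rddm_genome` (used for terminal-bin clipping).
#' @param bin_size bin width, default 100 bp.
#' @param min_cov minimum per-cytosine coverage in both samples, default 4.
#' @param min_sites minimum informative cytosines per bin, default 1.
#' @param pool_cg_strands collapse symmetric CG dinucleotides onto the
#'   plus-strand cytosine before binning (off by default: each strand's
#'   cytosine is a separate record).
#' @param pool_contexts pool all three contexts into a single "total"
#'   context (the experimental total-C DMR mode; test it with threshold
#'   0.1).
#' @return `meth_bins` data.table: chrom, start, end, context, n_sites,
#'   meth_wt, unmeth_wt, meth_mut, unmeth_mut, level_wt, level_mut,
#'   diff_level (mutant minus WT).
#' @export
bin_methylation <- function(wt, mut, genome, bin_size = 100L, min_cov = 4L,
                            min_sites = 1L, pool_cg_strands = FALSE,
                            pool_contexts = FALSE) {
  wt <- as.data.table(wt)
  mut <- as.data.table(mut)
  lens <- setNames(genome$index$length, genome$index$chrom)
  for (dt in list(wt, mut)) {
    if (!all(unique(dt$chrom) %in% names(lens)))
      .stopf("sample chromosome not present in genome")
  }
  shift_cg <- function(dt) {
    dt <- copy(dt)
    dt[context == "CG" & strand == "-", `:=`(pos = pos - 1L, strand = "+")]
    dt[, .(meth = sum(meth), unmeth = sum(unmeth)),
       by = .(chrom, pos, strand, context)]
  }
  if (pool_cg_strands) {
    wt <- shift_cg(wt)
    mut <- shift_cg(mut)
  }
  m <- merge(wt[, .(chrom, pos, strand, context, meth, unmeth)],
             mut[, .(chrom, pos, strand, context, meth, unmeth)],
             by = c("chrom", "pos", "strand", "context"),
             suffixes = c("_wt", "_mut"))
  m <- m[meth_wt + unmeth_wt >= min_cov & meth_mut + unmeth_mut >= min_cov]
  if (pool_contexts) m[, context := "total"]
  m[, bin := pos %/% as.integer(bin_size)]
  bins <- m[, .(n_sites = .N,
                meth_wt = sum(meth_wt), unmeth_wt = sum(unmeth_wt),
                meth_mut = sum(meth_mut), unmeth_mut = sum(unmeth_mut)),
            by = .(chrom, bin, context)]
  bins <- bins[n_sites >= min_sites]
  bins[, start := bin * as.integer(bin_size)]
  bins[, end := pmin(start + as.integer(bin_size), lens[chrom])]
  bins[, `:=`(level_wt = meth_wt / (meth_wt + unmeth_wt),
              level_mut = meth_mut / (meth_mut + unmeth_mut))]
  bins[, diff_level := level_mut - level_wt]
  bins[, bin := NULL]
  setorder(bins, chrom, context, start)
  setattr(bins, "class", c("meth_bins", class(bins)))
  bins[]
}

#' Default per-context methylation-difference thresholds
#' @export
dmr_thresholds <- c(CG = 0.4, CHG = 0.2, CHH = 0.1, total = 0.1)

#' Test methylation bins for differential methylation
#'
#' Fisher's exact test on the bin-pooled methylated/unmethylated counts of
#' the two samples; Benjamini-Hochberg adjustment within each context over
#' all testable bins. A bin is significant iff |level difference| exceeds
#' the context threshold AND q is strictly below `q_cutoff` (both
#' inequalities strict).
#'
#' @param bins output of [bin_methylation()].
#' @param thresholds named vector of per-context |difference| thresholds;
#'   defaults to mCG 0.4, mCHG 0.2, mCHH 0.1 (and 0.1 for the pooled
#'   "total" mode).
#' @param q_cutoff FDR cutoff, default 0.05.
#' @return the bin table with p, q, significant and direction columns
#'   added (direction is "hypo" when the mutant level is lower).
#' @export
test_bins <- function(bins, thresholds = dmr_thresholds, q_cutoff = 0.05) {
  bins <- copy(as.data.table(bins))
  if (nrow(bins) == 0L) {
    bins[, `:=`(p = numeric(), q = numeric(), significant = logical(),
                direction = character())]
    return(bins)
  }
  missing_ctx <- setdiff(unique(bins$context), names(thresholds))
  if (length(missing_ctx))
    .stopf("no threshold for context %s", paste(missing_ctx, collapse = ","))
  bins[, p := fisher_exact_2x2_vec(meth_wt, unmeth_wt, meth_mut,
                                   unmeth_mut)]
  bins[, q := bh_adjust(p), by = context]
  bins[, significant := abs(diff_level) > thresholds[context] &
         q < q_cutoff]
  bins[, direction := fifelse(diff_level < 0, "hypo", "hyper")]
  setattr(bins, "class", unique(c("meth_bins", class(bins))))
  bins[]
}

#' Join significant bins into DMRs
#'
#' Within each (chromosome, context, direction) stream, consecutive
#' significant bins whose gap (next start minus previous end) is at most
#' `join_gap` are merged into one differentially methylated region. Hypo
#' and hyper bins never merge; contexts never merge.
#'
#' @param sig_bins output of [test_bins()] (the `significant` column is
#'   honoured if present, otherwise all rows are used).
#' @param join_gap maximum joining distance, default 200 bp.
#' @return `dmr` data.table: chrom, start, end, context, direction,
#'   n_bins, mean_diff, min_q.
#' @export
call_dmrs <- function(sig_bins, join_gap = 200L) {
  b <- as.data.table(sig_bins)
  if ("significant" %in% names(b)) b <- b[significant == TRUE]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), n_bins = integer(),
                      mean_diff = numeric(), min_q = numeric())
  if (nrow(b) == 0L) return(empty)
  if (!"direction" %in% names(b))
    b[, direction := fifelse(diff_level < 0, "hypo", "hyper")]
  if (!"q" %in% names(b)) b[, q := NA_real_]
  setorder(b, chrom, context, direction, start)
  b[, gap := start - shift(end, fill = NA_integer_),
    by = .(chrom, context, direction)]
  b[, grp := cumsum(is.na(gap) | gap > join_gap),
    by = .(chrom, context, direction)]
  dmrs <- b[, .(start = min(start), end = max(end), n_bins = .N,
                mean_diff = mean(diff_level), min_q = min(q)),
            by = .(chrom, context, direction, grp)]
  dmrs[, grp := NULL]
  setcolorder(dmrs, c("chrom", "start", "end", "context", "direction",
                      "n_bins", "mean_diff", "min_q"))
  setorder(dmrs, chrom, context, direction, start)
  dmrs[]
}

#' Summary statistics for a DMR set
#'
#' @param dmrs `dmr` data.table.
#' @param digits rounding for the mean length (default 0, i.e. whole bp).
#' @return list: `n`, `mean_length`, `total_length_bp`.
#' @export
dmr_stats <- function(dmrs, digits = 0) {
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) == 0L)
    return(list(n = 0L, mean_length = 0, total_length_bp = 0))
  len <- dmrs$end - dmrs$start
  list(n = nrow(dmrs),
       mean_length = round_half_up(mean(len), digits),
       total_length_bp = sum(len))
}

#' One-call DMR pipeline for a WT/mutant pair
#'
#' Convenience wrapper: [bin_methylation()] then [test_bins()] then
#' [call_dmrs()].
#'
#' @inheritParams bin_methylation
#' @inheritParams test_bins
#' @inheritParams call_dmrs
#' @return list: `bins` (tested bin table), `dmrs`.
#' @export
call_dmr_pipeline <- function(wt, mut, genome, bin_size = 100L,
                              min_cov = 4L, min_sites = 1L,
                              thresholds = dmr_thresholds,
                              q_cutoff = 0.05, join_gap = 200L,
                              pool_cg_strands = FALSE,
                              pool_contexts = FALSE) {
  bins <- bin_methylation(wt, mut, genome, bin_size = bin_size,
                          min_cov = min_cov, min_sites = min_sites,
                          pool_cg_strands = pool_cg_strands,
                          pool_contexts = pool_contexts)
  tested <- test_bins(bins, thresholds = thresholds, q_cutoff = q_cutoff)
  list(bins = tested, dmrs = call_dmrs(tested, join_gap = join_gap))
}
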