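#' Filter small-RNA reads
#'
#' Drops reads that overlap the structural-RNA mask (rRNA/tRNA/snRNA/
#' snoRNA annotation), fall outside the size-selection window, or map to
#' multiple locations. The RPTM denominator (`total_mapped`) counts every
#' retained 18-30-nt read; downstream binning uses only reads of
#' `keep_len` (24 nt).
#'
#' @param reads data.table with chrom, start, end (0-based half-open),
#'   optionally strand, and columns `length_nt` and `multi` (logical
#'   multi-mapper flag; absent means all unique).
#' @param structural_mask data.table (chrom, start, end) or NULL.
#' @param len_range retained read-length window, default 18-30 nt.
#' @param keep_len read length used for binned counts, default 24.
#' @param unique_only drop multi-mappers, default TRUE.
#' @return list: `reads` (retained reads, all lengths), `total_mapped`,
#'   `keep_len`.
#' @export
filter_srna_reads <- function(reads, structural_mask = NULL,
                              len_range = c(18L, 30L), keep_len = 24L,
                              unique_only = TRUE) {
  reads <- as.data.table(reads)
  if (!"length_nt" %in% names(reads))
    .stopf("reads must carry a length_nt column")
  if (!"multi" %in% names(reads)) reads[, multi := FALSE]
  keep <- reads$length_nt >= len_range[1] & reads$length_nt <= len_range[2]
  if (unique_only) keep <- keep & !reads$multi
  reads <- reads[keep]
  if (!is.null(structural_mask) && nrow(structural_mask) && nrow(reads)) {
    chroms <- unique(c(reads$chrom, structural_mask$chrom))
    hit <- IRanges::overlapsAny(.irl(reads, chroms),
                                .irl(structural_mask, chroms))
    reads <- reads[!unlist(hit, use.names = FALSE)]
  }
  list(reads = reads[], total_mapped = nrow(reads), keep_len = keep_len)
}

#' Bin small-RNA reads and normalize to RPTM
#'
#' Each read of the kept length is assigned to the 100-bp bin containing
#' its 5' end (read start on the plus strand, last base on the minus
#' strand). Counts are normalized to reads per ten million:
#' `rptm = count * 1e7 / total_mapped`.
#'
#' @param filtered output of [filter_srna_reads()], or a data.table of
#'   reads together with `total_mapped`.
#' @param genome `rddm_genome`.
#' @param bin_size bin width, default 100.
#' @param total_mapped RPTM denominator; taken from `filtered` when it is
#'   a filter result.
#' @return `srna_bins` data.table (chrom, start, end, count, rptm) over
#'   all genome bins, with attribute `total_mapped`.
#' @export
bin_and_normalize <- function(filtered, genome, bin_size = 100L,
                              total_mapped = NULL) {
  if (is.list(filtered) && !is.data.frame(filtered)) {
    total_mapped <- total_mapped %||% filtered$total_mapped
    keep_len <- filtered$keep_len %||% 24L
    reads <- filtered$reads[length_nt == keep_len]
  } else {
    reads <- as.data.table(filtered)
    if (is.null(total_mapped)) .stopf("total_mapped required")
  }
  lens <- setNames(genome$index$length, genome$index$chrom)
  if (nrow(reads)) {
    if (!"strand" %in% names(reads)) reads[, strand := "+"]
    fivep <- fifelse(reads$strand == "-", reads$end - 1L, reads$start)
    if (any(fivep < 0L) || any(fivep >= lens[reads$chrom]))
      .stopf("read 5' end beyond chromosome bounds")
    cnt <- data.table(chrom = reads$chrom,
                      start = (fivep %/% as.integer(bin_size)) *
                        as.integer(bin_size))[
      , .(count = .N), by = .(chrom, start)]
  } else {
    cnt <- data.table(chrom = character(), start = integer(),
                      count = integer())
  }
  bins <- tile_genome(genome, bin_size)
  bins <- merge(bins, cnt, by = c("chrom", "start"), all.x = TRUE)
  bins[is.na(count), count := 0L]
  srna_bins(bins[, .(chrom, start, end, count)], total_mapped)
}

#' Wrap a per-bin count table as normalized siRNA bins
#'
#' @param counts data.table (chrom, start, end, count).
#' @param total_mapped RPTM denominator (retained 18-30-nt mapped reads).
#' @return `srna_bins` data.table with an `rptm` column and a
#'   `total_mapped` attribute.
#' @export
srna_bins <- function(counts, total_mapped) {
  if (is.null(total_mapped) || total_mapped <= 0)
    .stopf("total_mapped must be positive")
  dt <- copy(as.data.table(counts))
  .check_count(dt$count, "bin counts")
  dt[, rptm := count * 1e7 / total_mapped]
  setorder(dt, chrom, start)
  setattr(dt, "total_mapped", total_mapped)
  setattr(dt, "class", unique(c("srna_bins", class(dt))))
  dt[]
}

#' Call differential 24-nt siRNA regions (DSRs)
#'
#' Bins with RPTM strictly above `min_rptm` in either sample are retained;
#' each retained bin is tested with the exact conditional binomial rate
#' test on (count, library size) of the two samples; q-values are
#' Benjamini-Hochberg over the retained bins; significant bins (q < fdr)
#' that are adjacent (gap 0) and share a direction are merged into DSRs.
#'
#' @param wt,mut `srna_bins` objects on the same binning.
#' @param min_rptm retention threshold, default 5 (strict >).
#' @param fdr FDR cutoff, default 0.01.
#' @return list: `bins` (retained, tested bin table with p, q,
#'   significant, direction), `dsrs` (chrom, start, end, direction, n_bins,
#'   logFC, p, q).
#' @export
call_dsrs <- function(wt, mut, min_rptm = 5, fdr = 0.01) {
  n_wt <- attr(wt, "total_mapped")
  n_mut <- attr(mut, "total_mapped")
  if (is.null(n_wt) || is.null(n_mut) || n_wt <= 0 || n_mut <= 0)
    .stopf("both samples need a positive total_mapped")
  m <- merge(as.data.table(wt)[, .(chrom, start, end, count_wt = count)],
             as.data.table(mut)[, .(chrom, start, end, count_mut = count)],
             by = c("chrom", "start", "end"), all = TRUE)
  m[is.na(count_wt), count_wt := 0L]
  m[is.na(count_mut), count_mut := 0L]
  m[, `:=`(rptm_wt = count_wt * 1e7 / n_wt,
           rptm_mut = count_mut * 1e7 / n_mut)]
  m <- m[rptm_wt > min_rptm | rptm_mut > min_rptm]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_bins = integer(), logFC = numeric(),
                      p = numeric(), q = numeric())
  if (nrow(m) == 0L) return(list(bins = m, dsrs = empty))
  m[, p := conditional_binomial_test_vec(count_wt, count_mut, n_wt, n_mut)]
  m[, q := bh_adjust(p)]
  m[, direction := fifelse(count_mut / n_mut >= count_wt / n_wt,
                           "up", "down")]
  m[, significant := q < fdr]
  setorder(m, chrom, start)
  sig <- m[significant == TRUE]
  if (nrow(sig) == 0L) return(list(bins = m[], dsrs = empty))
  sig[, gap := start - shift(end, fill = NA_integer_),
      by = .(chrom, direction)]
  sig[, grp := cumsum(is.na(gap) | gap > 0L), by = .(chrom, direction)]
  dsrs <- sig[, .(start = min(start), end = max(end), n_bins = .N,
                  logFC = log2(((sum(count_mut) + 0.5) / n_mut) /
                                 ((sum(count_wt) + 0.5) / n_wt)),
                  p = min(p), q = min(q)),
              by = .(chrom, direction, grp)]
  dsrs[, grp := NULL]
  setcolorder(dsrs, c("chrom", "start", "end", "direction", "n_bins",
                      "logFC", "p", "q"))
  setorder(dsrs, chrom, start)
  list(bins = m[], dsrs = dsrs[])
}

#' Differential gene/TE expression via the exact conditional binomial test
#'
#' One WT and one mutant library; library sizes are the column sums.
#' Features with zero total count are untested (status NA). Status is
#' up/down iff q < `fdr` AND the normalized fold change reaches `fc` in
#' that direction.
#'
#' @param counts data.table (id, kind, count_wt, count_mut) or a 2-column
#'   matrix with feature rownames (columns WT, mutant).
#' @param fdr FDR cutoff, default 0.05.
#' @param fc fold-change cutoff, default 2.
#' @return data.table (id, kind, count_wt, count_mut, fold_change, p, q,
#'   status). `fold_change` is mutant over WT after library-size
#'   normalization (Inf when the WT count is 0).
#' @export
call_degs <- function(counts, fdr = 0.05, fc = 2) {
  if (is.matrix(counts)) {
    counts <- data.table(id = rownames(counts) %||%
                           paste0("feat", seq_len(nrow(counts))),
                         kind = "gene",
                         count_wt = counts[, 1], count_mut = counts[, 2])
  }
  dt <- copy(as.data.table(counts))
  if (!"kind" %in% names(dt)) dt[, kind := "gene"]
  .check_count(dt$count_wt, "WT counts")
  .check_count(dt$count_mut, "mutant counts")
  n_wt <- sum(dt$count_wt)
  n_mut <- sum(dt$count_mut)
  if (n_wt == 0 && n_mut == 0) {
    return(dt[0][, `:=`(fold_change = numeric(), p = numeric(),
                        q = numeric(), status = character())])
  }
  dt[, fold_change := (count_mut / n_mut) / (count_wt / n_wt)]
  tested <- dt$count_wt + dt$count_mut > 0
  dt[, p := NA_real_]
  dt[tested, p := conditional_binomial_test_vec(count_wt, count_mut,
                                                n_wt, n_mut)]
  dt[, q := NA_real_]
  dt[tested, q := bh_adjust(p)]
  dt[, status := NA_character_]
  dt[tested, status := fifelse(
    q < fdr & fold_change >= fc, "up",
    fifelse(q < fdr & fold_change <= 1 / fc, "down", "ns"))]
  dt[]
}

#' Per-region siRNA and methylation deltas (DSR scatter export)
#'
#' For each region the 24-nt siRNA change is the difference in
#' log10(RPTM + pseudocount) of the region-pooled counts, and the
#' methylation change per context is the difference in pooled
#' methylated/(methylated+unmethylated) level over all covered cytosines
#' of the region. Regions with no covered cytosine in a context get NA for
#' that context and are excluded from that context's correlation.
#'
#' @param regions data.table (chrom, start, end), e.g. DSRs.
#' @param srna_wt,srna_mut `srna_bins` objects.
#' @param cx_wt,cx_mut CX-style cytosine tables.
#' @param pseudocount added to RPTM before log10, default 1.
#' @return list: `table` (one row per region with dlog_rptm and
#'   dlevel_CG/CHG/CHH), `correlations` (context, method, estimate, n).
#'   When a correlation is undefined (fewer than 3 complete rows or zero
#'   variance) the estimate is NA.
#' @export
delta_scatter <- function(regions, srna_wt, srna_mut, cx_wt, cx_mut,
                          pseudocount = 1) {
  regions <- .check_regions(as.data.table(regions))
  n_wt <- attr(srna_wt, "total_mapped")
  n_mut <- attr(srna_mut, "total_mapped")
  regions <- copy(regions)[, feature_id := .I]

  pool_bins <- function(bins) {
    b <- as.data.table(bins)
    chroms <- unique(c(regions$chrom, b$chrom))
    hits <- IRanges::findOverlaps(.irl(regions, chroms), .irl(b, chroms))
    per_chrom <- lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (length(h) == 0L) return(NULL)
      ridx <- which(regions$chrom == chroms[i])[S4Vectors::queryHits(h)]
      bidx <- which(b$chrom == chroms[i])[S4Vectors::subjectHits(h)]
      data.table(feature_id = regions$feature_id[ridx],
                 count = b$count[bidx])
    })
    rbindlist(per_chrom)[, .(count = sum(count)), by = feature_id]
  }
  cw <- pool_bins(srna_wt)
  cm <- pool_bins(srna_mut)
  out <- copy(regions)
  out <- merge(out, setnames(cw, "count", "count_wt"), by = "feature_id",
               all.x = TRUE)
  out <- merge(out, setnames(cm, "count", "count_mut"), by = "feature_id",
               all.x = TRUE)
  out[is.na(count_wt), count_wt := 0L]
  out[is.na(count_mut), count_mut := 0L]
  out[, dlog_rptm := log10(count_mut * 1e7 / n_mut + pseudocount) -
        log10(count_wt * 1e7 / n_wt + pseudocount)]

  pool_cx <- function(cx) {
    cx <- as.data.table(cx)
    chroms <- unique(c(regions$chrom, cx$chrom))
    cxiv <- data.table(chrom = cx$chrom, start = cx$pos,
                       end = cx$pos + 1L)
    hits <- IRanges::findOverlaps(.irl(regions, chroms),
                                  .irl(cxiv, chroms))
    per_chrom <- lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (length(h) == 0L) return(NULL)
      ridx <- which(regions$chrom == chroms[i])[S4Vectors::queryHits(h)]
      cidx <- which(cx$chrom == chroms[i])[S4Vectors::subjectHits(h)]
      data.table(feature_id = regions$feature_id[ridx],
                 context = cx$context[cidx],
                 meth = cx$meth[cidx], unmeth = cx$unmeth[cidx])
    })
    rbindlist(per_chrom)[, .(meth = sum(meth), unmeth = sum(unmeth)),
                         by = .(feature_id, context)]
  }
  pw <- pool_cx(cx_wt)
  pm <- pool_cx(cx_mut)
  for (ctx in c("CG", "CHG", "CHH")) {
    a <- pw[context == ctx & meth + unmeth > 0,
            .(feature_id, lw = meth / (meth + unmeth))]
    b <- pm[context == ctx & meth + unmeth > 0,
            .(feature_id, lm = meth / (meth + unmeth))]
    ab <- merge(a, b, by = "feature_id")
    col <- paste0("dlevel_", ctx)
    out[, (col) := NA_real_]
    if (nrow(ab)) out[ab$feature_id, (col) := ab$lm - ab$lw]
  }

  cors <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx) {
    col <- paste0("dlevel_", ctx)
    ok <- is.finite(out$dlog_rptm) & !is.na(out[[col]])
    est <- function(method) {
      x <- out$dlog_rptm[ok]
      y <- out[[col]][ok]
      if (sum(ok) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
        return(NA_real_)
      stats::cor(x, y, method = method)
    }
    data.table(context = ctx,
               method = c("pearson", "spearman"),
               estimate = c(est("pearson"), est("spearman")),
               n = sum(ok))
  }))
  list(table = out[], correlations = cors)
}
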