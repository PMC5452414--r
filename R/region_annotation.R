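#' Partition the genome into gene / TE / gene-TE / intergenic
#'
#' Every base pair is assigned to exactly one class: covered by gene
#' annotation only, TE annotation only, both ("gene/TE"), or neither
#' (intergenic). The classes are disjoint and tile the genome exactly.
#'
#' @param features data.table (chrom, start, end, kind) with kind in
#'   {gene, TE}.
#' @param genome `rddm_genome`.
#' @return data.table (chrom, start, end, class), sorted.
#' @export
build_partition <- function(features, genome) {
  features <- .check_regions(as.data.table(features), "features")
  lens <- setNames(genome$index$length, genome$index$chrom)
  if (nrow(features)) {
    if (!all(features$chrom %in% names(lens)))
      .stopf("feature chromosome not in genome")
    if (any(features$end > lens[features$chrom]))
      .stopf("feature beyond chromosome end")
  }
  chroms <- genome$index$chrom
  g_ir <- IRanges::reduce(.irl(features[kind == "gene"], chroms))
  t_ir <- IRanges::reduce(.irl(features[kind == "TE"], chroms))
  gen_ir <- .genome_irl(genome)
  both <- IRanges::intersect(g_ir, t_ir)
  gene_only <- IRanges::setdiff(g_ir, t_ir)
  te_only <- IRanges::setdiff(t_ir, g_ir)
  inter <- IRanges::setdiff(gen_ir, IRanges::union(g_ir, t_ir))
  out <- rbindlist(list(
    .irl_dt(gene_only)[, class := "gene"],
    .irl_dt(te_only)[, class := "TE"],
    .irl_dt(both)[, class := "gene/TE"],
    .irl_dt(inter)[, class := "intergenic"]))
  setorder(out, chrom, start)
  out[]
}

#' Distribute region base pairs over a feature partition
#'
#' Base-pair-weighted fractions of a (merged) region set that fall into
#' each partition class; fractions sum to 1. A majority-class mode is also
#' available, assigning each region wholly to the class covering most of
#' its length.
#'
#' @param regions data.table (chrom, start, end).
#' @param partition output of [build_partition()].
#' @param mode "bp" (default) or "majority".
#' @return named numeric vector of fractions over the partition classes,
#'   with attribute `n` = number of regions (all-zero with n = 0 for an
#'   empty region set).
#' @export
distribute_regions <- function(regions, partition, mode = c("bp",
                                                            "majority")) {
  mode <- match.arg(mode)
  regions <- .check_regions(as.data.table(regions))
  classes <- c("gene", "TE", "gene/TE", "intergenic")
  if (nrow(regions) == 0L) {
    out <- setNames(rep(0, length(classes)), classes)
    attr(out, "n") <- 0L
    return(out)
  }
  partition <- as.data.table(partition)
  chroms <- unique(c(regions$chrom, partition$chrom))
  if (mode == "bp") {
    r_ir <- IRanges::reduce(.irl(regions, chroms))
    bp <- vapply(classes, function(cl) {
      .total_bp(IRanges::intersect(r_ir, .irl(partition[class == cl],
                                              chroms)))
    }, 0)
  } else {
    bp <- setNames(rep(0, length(classes)), classes)
    for (i in seq_len(nrow(regions))) {
      reg <- regions[i]
      ov <- vapply(classes, function(cl) {
        .total_bp(IRanges::intersect(
          .irl(reg, chroms), .irl(partition[class == cl], chroms)))
      }, 0)
      win <- classes[which.max(ov)]
      bp[win] <- bp[win] + (reg$end - reg$start)
    }
  }
  tot <- sum(bp)
  out <- if (tot > 0) bp / tot else setNames(rep(0, length(classes)),
                                             classes)
  attr(out, "n") <- nrow(regions)
  out
}

#' Overlap accounting between two region sets
#'
#' @param a,b data.tables (chrom, start, end).
#' @param min_bp a region of `a` counts as overlapping `b` if it
#'   intersects some region of `b` by at least this many bp (default 1).
#' @return list: `n_a_overlapping_b`, `n_b_overlapping_a`,
#'   `n_shared_pairs`, `total_bp_a`, `total_bp_b`, `overlap_bp` (bp of the
#'   intersection of the two merged sets), `jaccard_bp`.
#' @export
overlap_sets <- function(a, b, min_bp = 1L) {
  a <- .check_regions(as.data.table(a), "a")
  b <- .check_regions(as.data.table(b), "b")
  chroms <- unique(c(a$chrom, b$chrom))
  a_ir <- .irl(a, chroms)
  b_ir <- .irl(b, chroms)
  total_a <- .total_bp(a_ir)
  total_b <- .total_bp(b_ir)
  ov_ir <- IRanges::intersect(IRanges::reduce(a_ir), IRanges::reduce(b_ir))
  overlap_bp <- .total_bp(ov_ir)
  union_bp <- total_a + total_b - overlap_bp
  count_hits <- function(x_ir, y_ir) {
    hits <- IRanges::findOverlaps(x_ir, y_ir, minoverlap = min_bp)
    n_pairs <- sum(vapply(seq_along(hits), function(i) length(hits[[i]]),
                          0L))
    n_any <- sum(vapply(seq_along(hits), function(i)
      length(unique(S4Vectors::queryHits(hits[[i]]))), 0L))
    c(n_any = n_any, n_pairs = n_pairs)
  }
  ha <- count_hits(a_ir, b_ir)
  hb <- count_hits(b_ir, a_ir)
  list(n_a_overlapping_b = unname(ha["n_any"]),
       n_b_overlapping_a = unname(hb["n_any"]),
       n_shared_pairs = unname(ha["n_pairs"]),
       total_bp_a = total_a, total_bp_b = total_b,
       overlap_bp = overlap_bp,
       jaccard_bp = if (union_bp > 0) overlap_bp / union_bp else 0)
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `digits` decimals
#' (the reporting convention for overlap percentages).
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @param digits decimal digits, default 1.
#' @return percentage on the 0-100 scale.
#' @examples
#' percent_overlap(6117, 6670) # 91.7
#' @export
percent_overlap <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) .stopf("denominator must be positive")
  round_half_up(100 * numerator / denominator, digits)
}

#' Associate features with DMRs within flanked bodies
#'
#' A (feature, DMR) pair is reported iff the DMR intersects the feature
#' body extended by `flank` bp on both sides (clipped to the chromosome).
#'
#' @param features data.table (chrom, start, end, id, ...).
#' @param dmrs data.table (chrom, start, end, ...).
#' @param genome `rddm_genome` used for clipping; NULL skips clipping.
#' @param flank extension in bp, default 1000.
#' @return list: `pairs` (feature_id, dmr_chrom, dmr_start, dmr_end),
#'   `n_pairs`, `n_features` (distinct features with >= 1 pair), `n_dmrs`
#'   (distinct DMRs involved).
#' @export
flank_associate <- function(features, dmrs, genome = NULL, flank = 1000L) {
  features <- .check_regions(as.data.table(features), "features")
  dmrs <- .check_regions(as.data.table(dmrs), "dmrs")
  if (!"id" %in% names(features))
    features <- copy(features)[, id := paste0("feat", .I)]
  ext <- copy(features)
  ext[, start := pmax(0L, start - as.integer(flank))]
  ext[, end := end + as.integer(flank)]
  if (!is.null(genome)) {
    lens <- setNames(genome$index$length, genome$index$chrom)
    ext[, end := pmin(end, lens[chrom])]
  }
  chroms <- unique(c(ext$chrom, dmrs$chrom))
  hits <- IRanges::findOverlaps(.irl(ext, chroms), .irl(dmrs, chroms))
  pairs <- rbindlist(lapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    if (length(h) == 0L) return(NULL)
    fidx <- which(ext$chrom == chroms[i])[S4Vectors::queryHits(h)]
    didx <- which(dmrs$chrom == chroms[i])[S4Vectors::subjectHits(h)]
    data.table(feature_id = ext$id[fidx],
               dmr_chrom = dmrs$chrom[didx],
               dmr_start = dmrs$start[didx],
               dmr_end = dmrs$end[didx])
  }))
  if (is.null(pairs) || nrow(pairs) == 0L)
    pairs <- data.table(feature_id = character(),
                        dmr_chrom = character(),
                        dmr_start = integer(), dmr_end = integer())
  setorder(pairs, feature_id, dmr_chrom, dmr_start)
  list(pairs = pairs[],
       n_pairs = nrow(pairs),
       n_features = length(unique(pairs$feature_id)),
       n_dmrs = nrow(unique(pairs[, .(dmr_chrom, dmr_start, dmr_end)])))
}

#' Promoter methylation levels per feature
#'
#' Pools cytosine counts over the `flank`-bp region immediately upstream
#' of each feature's strand-aware start (upstream of `start` for plus
#' strand, downstream of `end` for minus strand), per context and per
#' sample.
#'
#' @param features data.table (chrom, start, end, strand, id).
#' @param cx_samples named list of CX-style cytosine tables.
#' @param flank promoter length, default 1000 bp.
#' @return data.table (feature_id, sample_id, context, meth, unmeth,
#'   level, n_sites); features without informative cytosines in a context
#'   carry NA level with n_sites = 0.
#' @export
promoter_methylation <- function(features, cx_samples, flank = 1000L) {
  features <- .check_regions(as.data.table(features), "features")
  if (!all(c("strand", "id") %in% names(features)))
    .stopf("features need strand and id columns")
  if (!all(features$strand %in% c("+", "-")))
    .stopf("feature strand must be + or -")
  prom <- copy(features)
  prom[, `:=`(pstart = fifelse(strand == "+",
                               pmax(0L, start - as.integer(flank)), end),
              pend = fifelse(strand == "+", start,
                             end + as.integer(flank)))]
  prom <- prom[pend > pstart, .(chrom, start = pstart, end = pend, id)]
  grid <- data.table(expand.grid(feature_id = features$id,
                                 sample_id = names(cx_samples),
                                 context = c("CG", "CHG", "CHH"),
                                 stringsAsFactors = FALSE))
  res <- rbindlist(lapply(names(cx_samples), function(sn) {
    cx <- as.data.table(cx_samples[[sn]])
    chroms <- unique(c(prom$chrom, cx$chrom))
    cxiv <- data.table(chrom = cx$chrom, start = cx$pos, end = cx$pos + 1L)
    hits <- IRanges::findOverlaps(.irl(prom, chroms), .irl(cxiv, chroms))
    rows <- rbindlist(lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (length(h) == 0L) return(NULL)
      pidx <- which(prom$chrom == chroms[i])[S4Vectors::queryHits(h)]
      cidx <- which(cx$chrom == chroms[i])[S4Vectors::subjectHits(h)]
      data.table(feature_id = prom$id[pidx], context = cx$context[cidx],
                 meth = cx$meth[cidx], unmeth = cx$unmeth[cidx])
    }))
    if (is.null(rows) || nrow(rows) == 0L) return(NULL)
    rows[meth + unmeth > 0,
         .(sample_id = sn, meth = sum(meth), unmeth = sum(unmeth),
           n_sites = .N),
         by = .(feature_id, context)]
  }))
  out <- merge(grid, res,
               by = c("feature_id", "sample_id", "context"), all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[, level := fifelse(n_sites > 0, meth / (meth + unmeth), NA_real_)]
  setorder(out, feature_id, sample_id, context)
  out[]
}

#' Chromatin-state enrichment of a region set
#'
#' For each of the nine states: observed bp of overlap between the merged
#' region set and the state's segments; expected bp under uniform
#' placement (total region bp times the state's genome fraction); fold =
#' observed/expected; a one-sided binomial enrichment p-value on `unit`-bp
#' units (n = region bp / unit, success probability = state genome
#' fraction); Benjamini-Hochberg q over the nine states. An optional
#' permutation mode shuffles the regions within chromosomes and reports an
#' empirical upper-tail p instead.
#'
#' @param regions data.table (chrom, start, end).
#' @param states data.table (chrom, start, end, state).
#' @param genome `rddm_genome`.
#' @param unit independence unit in bp for the binomial model, default
#'   100 (the bin width the regions were built from).
#' @param method "binomial" (default) or "permutation".
#' @param n_perm permutations (permutation mode), default 1000.
#' @param seed seed for the permutation mode.
#' @return data.table (state, state_bp, genome_frac, observed_bp,
#'   expected_bp, region_frac, fold, p, q, neg_log10_q).
#' @export
state_enrichment <- function(regions, states, genome, unit = 100L,
                             method = c("binomial", "permutation"),
                             n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  regions <- .check_regions(as.data.table(regions))
  states <- as.data.table(states)
  chroms <- genome$index$chrom
  genome_bp <- sum(as.numeric(genome$index$length))
  r_ir <- IRanges::reduce(.irl(regions, chroms))
  region_bp <- .total_bp(r_ir)
  if (region_bp == 0) .stopf("empty region set")

  obs_one <- function(rir) {
    vapply(1:9, function(st) {
      .total_bp(IRanges::intersect(rir, .irl(states[state == st],
                                             chroms)))
    }, 0)
  }
  state_bp <- vapply(1:9, function(st)
    .total_bp(.irl(states[state == st], chroms)), 0)
  observed <- obs_one(r_ir)
  genome_frac <- state_bp / genome_bp
  expected <- region_bp * genome_frac
  fold <- ifelse(expected > 0, observed / expected, NA_real_)

  if (method == "binomial") {
    n_units <- max(1L, round(region_bp / unit))
    obs_units <- round(observed / unit)
    p <- vapply(1:9, function(i) {
      if (state_bp[i] == 0) return(NA_real_)
      stats::pbinom(pmin(obs_units[i], n_units) - 1, n_units,
                    genome_frac[i], lower.tail = FALSE)
    }, 0)
  } else {
    set.seed(seed)
    lens_dt <- regions[, .(chrom, width = end - start)]
    chrom_len <- setNames(genome$index$length, chroms)
    exceed <- rep(0L, 9)
    for (b in seq_len(n_perm)) {
      st <- floor(runif(nrow(lens_dt)) *
                    (chrom_len[lens_dt$chrom] - lens_dt$width))
      perm <- data.table(chrom = lens_dt$chrom, start = as.integer(st),
                         end = as.integer(st + lens_dt$width))
      ob <- obs_one(IRanges::reduce(.irl(perm, chroms)))
      exceed <- exceed + as.integer(ob >= observed)
    }
    p <- (1 + exceed) / (1 + n_perm)
    p[state_bp == 0] <- NA_real_
  }
  ok <- !is.na(p)
  q <- rep(NA_real_, 9)
  if (any(ok)) q[ok] <- bh_adjust(p[ok])
  data.table(state = 1:9, state_bp = state_bp,
             genome_frac = genome_frac,
             observed_bp = observed, expected_bp = expected,
             region_frac = observed / region_bp,
             fold = fold, p = p, q = q,
             neg_log10_q = -log10(pmax(q, 1e-300)))
}
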