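#' Configuration for the synthetic RdDM world
#'
#' The generator plants a small Arabidopsis-like world: a random genome, a
#' set of non-overlapping RdDM loci, heterochromatic loci, genes and
#' structural-RNA loci, plus a nine-state chromatin segmentation in which
#' RdDM and heterochromatic loci are preferentially state 8. Four genotypes
#' are modelled: WT; `pkl` with partial CHH losses (default delta 0.3) at a
#' configurable fraction of RdDM loci and partial gains at a disjoint
#' low-methylation subset; `nrpd1` and `nrpe1` with CHH collapsed to the
#' basal level at every RdDM locus. siRNA production at RdDM loci drops
#' 5-fold in `pkl` (at the hypo subset), to basal in `nrpd1`, and 4-fold in
#' `nrpe1`. A configurable subset of TEs is transcriptionally derepressed
#' in `pkl`.
#'
#' @param genome_size bp per chromosome.
#' @param n_chroms number of chromosomes.
#' @param seed root seed; every downstream draw is reproducible from it.
#' @param n_rddm_loci,n_het_loci,n_genes,n_structural locus counts.
#' @param locus_len,gene_len,struct_len length ranges (bp) for RdDM and
#'   heterochromatic loci, genes, and structural-RNA loci.
#' @param min_gap minimum spacing between planted loci (keeps planted
#'   effects separable by the 200-bp DMR joining rule).
#' @param coverage_mean mean bisulfite coverage per cytosine (Poisson).
#' @param beta_concentration concentration of the site-level Beta noise
#'   around each locus methylation level.
#' @param srna_library_size expected total mapped 24-nt reads per library.
#' @param nb_dispersion dispersion of the shared per-bin gamma efficiency;
#'   marginal bin counts are negative binomial with this dispersion.
#' @param srna_other_len_fraction,srna_structural_fraction,srna_multi_fraction
#'   contaminant fractions for the optional per-read output: non-24-nt
#'   (21-23/25) reads, reads inside structural-RNA loci, multi-mappers.
#' @param pkl_hypo_fraction,pkl_hyper_fraction fractions of RdDM loci given
#'   a `pkl` CHH loss / gain (disjoint subsets).
#' @param pkl_delta_chh planted CHH methylation change in `pkl`.
#' @param pkl_srna_fold,nrpe1_srna_fold siRNA fold-reductions.
#' @param basal_chh basal CHH level for nrpd1/nrpe1 at RdDM loci.
#' @param expr_library_size expected total mRNA-seq counts per library.
#' @param n_te_derepressed,te_derepression_fold TEs transcriptionally
#'   derepressed in `pkl` and their fold.
#' @param n_deg_up,n_deg_down,deg_fold differentially expressed genes
#'   planted in `pkl`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 2e6, n_chroms = 1, seed = 1,
                       n_rddm_loci = 200, n_het_loci = 100, n_genes = 300,
                       n_structural = 20,
                       locus_len = c(300, 800), gene_len = c(1000, 3000),
                       struct_len = c(100, 300), min_gap = 300,
                       coverage_mean = 20, beta_concentration = 50,
                       srna_library_size = 2e6, nb_dispersion = 0.2,
                       srna_other_len_fraction = 0.1,
                       srna_structural_fraction = 0.05,
                       srna_multi_fraction = 0.05,
                       pkl_hypo_fraction = 0.5, pkl_hyper_fraction = 0.1,
                       pkl_delta_chh = 0.3,
                       pkl_srna_fold = 5, nrpe1_srna_fold = 4,
                       basal_chh = 0.02,
                       expr_library_size = 5e6,
                       n_te_derepressed = 25, te_derepression_fold = 10,
                       n_deg_up = 30, n_deg_down = 30, deg_fold = 4) {
  cfg <- as.list(environment())
  cfg$genotypes <- c("WT", "pkl", "nrpd1", "nrpe1")
  # class-level methylation (cg, chg, chh), identical across genotypes
  cfg$background_levels <- c(cg = 0.02, chg = 0.01, chh = 0.01)
  cfg$het_levels <- c(cg = 0.85, chg = 0.60, chh = 0.12)
  cfg$gene_levels <- c(cg = 0.05, chg = 0.01, chh = 0.01)
  stopifnot(genome_size > 0, n_chroms >= 1, coverage_mean >= 0,
            pkl_hypo_fraction >= 0, pkl_hypo_fraction <= 1,
            pkl_hyper_fraction >= 0,
            pkl_hypo_fraction + pkl_hyper_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# non-overlapping placement with a spacing margin; bounded retries
.place_loci <- function(n, len_range, chrom_lens, placed, min_gap,
                        max_rounds = 200L) {
  if (n == 0L)
    return(list(loci = data.table(chrom = character(), start = integer(),
                                  end = integer()),
                placed = placed))
  out <- vector("list", 0L)
  need <- n
  for (round in seq_len(max_rounds)) {
    if (need == 0L) break
    ci <- sample(length(chrom_lens), need, replace = TRUE)
    len <- sample(len_range[1]:len_range[2], need, replace = TRUE)
    maxs <- chrom_lens[ci] - len
    if (any(maxs < 1)) .stopf("genome too small for requested locus length")
    st <- floor(runif(need) * maxs)
    cand <- data.table(chrom = names(chrom_lens)[ci], start = st,
                       end = st + len)
    # greedy: accept candidates that keep min_gap clearance from everything
    # already accepted
    infl <- copy(cand)[, `:=`(start = pmax(0L, start - min_gap),
                              end = end + min_gap)]
    keep <- logical(nrow(cand))
    taken <- placed[, .(chrom, start, end)]
    for (i in seq_len(nrow(cand))) {
      iv <- infl[i]
      hit <- taken[chrom == iv$chrom & start < iv$end & end > iv$start]
      if (nrow(hit) == 0L) {
        keep[i] <- TRUE
        taken <- rbind(taken, cand[i, .(chrom, start, end)])
      }
    }
    got <- cand[keep]
    if (nrow(got)) {
      out[[length(out) + 1L]] <- got
      placed <- rbind(placed, got[, .(chrom, start, end)])
      need <- need - nrow(got)
    }
  }
  if (need > 0L)
    .stopf("could not place %d loci without overlap: genome too small", need)
  list(loci = rbindlist(out), placed = placed)
}

.build_states <- function(index, loci) {
  segs <- vector("list", 0L)
  for (i in seq_len(nrow(index))) {
    chromi <- index$chrom[i]
    L <- index$length[i]
    lc <- loci[chrom == chromi & class %in% c("RdDM", "heterochromatin")]
    setorder(lc, start)
    cur <- 0L
    add <- function(s, e, st) {
      if (e > s) segs[[length(segs) + 1L]] <<-
          data.table(chrom = chromi, start = s, end = e, state = st)
    }
    fill_bg <- function(s, e) {
      while (s < e) {
        w <- min(sample(2000:8000, 1L), e - s)
        add(s, s + w, sample(1:7, 1L))
        s <- s + w
      }
    }
    for (j in seq_len(nrow(lc))) {
      fill_bg(cur, lc$start[j])
      add(lc$start[j], lc$end[j], sample(c(8L, 8L, 8L, 4L, 5L, 9L), 1L))
      cur <- lc$end[j]
    }
    fill_bg(cur, L)
  }
  st <- rbindlist(segs)
  setorder(st, chrom, start)
  st[]
}

#' Simulate a genome with planted RdDM effects
#'
#' Generates the sequence, locus placement, gene/TE annotation, chromatin
#' states, cytosine table (with per-site shared noise), per-bin siRNA
#' efficiencies, and the full truth tables (methylation levels, siRNA
#' weights and expression folds per genotype). Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `rddm_sim`: list with `genome`, `features`
#'   (genes and TEs), `structural` (structural-RNA loci), `states`,
#'   `truth` (list: loci, meth, srna, expr), `cytosines`, `srna_bins`,
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  idx_names <- paste0("chr", seq_len(config$n_chroms))
  seqs <- vapply(idx_names, function(nm)
    paste(sample(c("A", "C", "G", "T"), config$genome_size,
                 replace = TRUE), collapse = ""), "")
  genome <- genome_from_seqs(seqs)
  chrom_lens <- setNames(genome$index$length, genome$index$chrom)

  placed <- data.table(chrom = character(), start = integer(),
                       end = integer())
  pr <- .place_loci(config$n_rddm_loci, config$locus_len, chrom_lens,
                    placed, config$min_gap)
  rddm <- pr$loci[, class := rep("RdDM", .N)]
  ph <- .place_loci(config$n_het_loci, config$locus_len, chrom_lens,
                    pr$placed, config$min_gap)
  het <- ph$loci[, class := rep("heterochromatin", .N)]
  pg <- .place_loci(config$n_genes, config$gene_len, chrom_lens,
                    ph$placed, config$min_gap)
  genes <- pg$loci[, class := rep("gene", .N)]
  ps <- .place_loci(config$n_structural, config$struct_len, chrom_lens,
                    pg$placed, config$min_gap)
  struct <- ps$loci[, class := rep("structural", .N)]

  loci <- rbind(rddm, het, genes, struct)
  setorder(loci, chrom, start)
  loci[, locus_id := .I]

  # pkl effect subsets among RdDM loci (disjoint)
  rid <- loci[class == "RdDM", locus_id]
  n_hypo <- round(config$pkl_hypo_fraction * length(rid))
  n_hyper <- round(config$pkl_hyper_fraction * length(rid))
  shuf <- sample(rid)
  hypo_ids <- shuf[seq_len(n_hypo)]
  hyper_ids <- shuf[n_hypo + seq_len(n_hyper)]
  loci[, subclass := "stable"]
  loci[locus_id %in% hypo_ids, subclass := "pkl_hypo"]
  loci[locus_id %in% hyper_ids, subclass := "pkl_hyper"]
  loci[class != "RdDM", subclass := NA_character_]

  # per-locus WT methylation at RdDM loci; hypo subset starts high enough
  # that subtracting pkl_delta_chh leaves a partial (not eliminated) level
  d <- config$pkl_delta_chh
  nr <- nrow(loci)
  wt_chh <- numeric(nr)
  wt_chh[loci$subclass %in% "pkl_hypo"] <-
    runif(sum(loci$subclass %in% "pkl_hypo"), d + config$basal_chh, 0.40)
  wt_chh[loci$subclass %in% "pkl_hyper"] <-
    runif(sum(loci$subclass %in% "pkl_hyper"), 0.02, 0.05)
  wt_chh[loci$subclass %in% "stable"] <-
    runif(sum(loci$subclass %in% "stable"), 0.10, 0.40)
  wt_chg <- runif(nr, 0.20, 0.60)
  wt_cg <- runif(nr, 0.75, 0.85)

  mk_levels <- function(genotype) {
    lv <- data.table(locus_id = loci$locus_id, genotype = genotype,
                     cg = NA_real_, chg = NA_real_, chh = NA_real_)
    is_rddm <- loci$class == "RdDM"
    lv[is_rddm, `:=`(cg = wt_cg[is_rddm], chg = wt_chg[is_rddm],
                     chh = wt_chh[is_rddm])]
    for (cl in c("heterochromatin", "gene", "structural")) {
      base <- switch(cl, heterochromatin = config$het_levels,
                     gene = config$gene_levels,
                     structural = config$background_levels)
      sel <- loci$class == cl
      lv[sel, `:=`(cg = base[["cg"]], chg = base[["chg"]],
                   chh = base[["chh"]])]
    }
    if (genotype == "pkl") {
      hy <- loci$subclass %in% "pkl_hypo"
      lv[hy, `:=`(chh = pmax(config$basal_chh, chh - d),
                  chg = chg * 0.6, cg = cg * 0.9)]
      hp <- loci$subclass %in% "pkl_hyper"
      lv[hp, chh := pmin(0.95, chh + d)]
    } else if (genotype %in% c("nrpd1", "nrpe1")) {
      rd <- loci$class == "RdDM"
      lv[rd, `:=`(chh = config$basal_chh, chg = 0.05)]
    }
    lv
  }
  truth_meth <- rbindlist(lapply(config$genotypes, mk_levels))

  # siRNA per-bin weight (relative to background 1) per locus x genotype
  wt_w <- numeric(nr)
  wt_w[loci$class == "RdDM"] <- 40
  wt_w[loci$class == "heterochromatin"] <- 5
  wt_w[loci$class %in% c("gene", "structural")] <- 1
  mk_srna <- function(genotype) {
    w <- wt_w
    if (genotype == "pkl") {
      w[loci$subclass %in% "pkl_hypo"] <-
        w[loci$subclass %in% "pkl_hypo"] / config$pkl_srna_fold
      w[loci$subclass %in% "pkl_hyper"] <-
        w[loci$subclass %in% "pkl_hyper"] * config$pkl_srna_fold
    } else if (genotype == "nrpd1") {
      w[loci$class == "RdDM"] <- 1
    } else if (genotype == "nrpe1") {
      w[loci$class == "RdDM"] <-
        w[loci$class == "RdDM"] / config$nrpe1_srna_fold
    }
    data.table(locus_id = loci$locus_id, genotype = genotype, weight = w)
  }
  truth_srna <- rbindlist(lapply(config$genotypes, mk_srna))

  # annotation: all het loci and half the RdDM loci are TEs; genes get
  # strands; a few TEs are nested inside genes to exercise the gene/TE class
  te_rddm <- sort(sample(rid, floor(length(rid) / 2)))
  te_loci <- loci[locus_id %in% c(te_rddm, loci[class == "heterochromatin",
                                                locus_id])]
  tes <- te_loci[, .(chrom, start, end, strand = "+",
                     kind = "TE", locus_id)]
  gn <- loci[class == "gene",
             .(chrom, start, end,
               strand = sample(c("+", "-"), .N, replace = TRUE),
               kind = "gene", locus_id)]
  feats <- rbind(gn, tes)
  setorder(feats, chrom, start)
  feats[, id := paste0(fifelse(kind == "TE", "TE", "gene"),
                       sprintf("%04d", seq_len(.N))), by = kind]
  n_nest <- min(10L, nrow(gn))
  if (n_nest > 0L) {
    host <- feats[kind == "gene"][sample(.N, n_nest)]
    nested <- host[, .(chrom, start = start + 100L,
                       end = pmin(end, start + 100L + 300L),
                       strand, kind = "TE", locus_id = NA_integer_,
                       id = paste0("TEn", sprintf("%03d", seq_len(n_nest))))]
    feats <- rbind(feats, nested)
    setorder(feats, chrom, start)
  }

  # expression truth over annotated features
  fe <- feats[, .(feature_id = id, kind, locus_id)]
  fe[, base_rate := rlnorm(.N, meanlog = 0, sdlog = 1)]
  fe[, eff := rgamma(.N, shape = 1 / config$nb_dispersion,
                     scale = config$nb_dispersion)]
  te_ids <- fe[kind == "TE" & !is.na(locus_id), feature_id]
  dere <- sample(te_ids, min(config$n_te_derepressed, length(te_ids)))
  gene_ids <- fe[kind == "gene", feature_id]
  up <- sample(gene_ids, min(config$n_deg_up, length(gene_ids)))
  down <- sample(setdiff(gene_ids, up),
                 min(config$n_deg_down, length(gene_ids) - length(up)))
  mk_expr <- function(genotype) {
    ex <- data.table(feature_id = fe$feature_id, genotype = genotype,
                     fold = 1)
    if (genotype == "pkl") {
      ex[feature_id %in% dere, fold := config$te_derepression_fold]
      ex[feature_id %in% up, fold := config$deg_fold]
      ex[feature_id %in% down, fold := 1 / config$deg_fold]
    } else if (genotype %in% c("nrpd1", "nrpe1")) {
      ex[feature_id %in% head(dere, 6), fold := 5]
    }
    ex
  }
  truth_expr <- rbindlist(lapply(config$genotypes, mk_expr))

  states <- .build_states(genome$index, loci)

  # cytosine table with locus assignment and shared site-level noise
  cyt <- derive_contexts(genome)
  locs <- copy(loci)[, `:=`(s = start, e = end)]
  setkey(locs, chrom, s, e)
  cyt[, locus_id := NA_integer_]
  for (ch in genome$index$chrom) {
    lc <- locs[chrom == ch]
    if (nrow(lc) == 0L) next
    sel <- cyt$chrom == ch
    iv <- findInterval(cyt$pos[sel], lc$s)
    inside <- iv >= 1L & cyt$pos[sel] < lc$e[pmax(iv, 1L)]
    lid <- rep(NA_integer_, sum(sel))
    lid[inside] <- lc$locus_id[iv[inside]]
    cyt[sel, locus_id := lid]
  }
  cyt[, site_u := runif(.N)]

  # 100-bp siRNA bin frame with shared gamma efficiency and locus overlap
  bins <- tile_genome(genome, 100L)
  bins[, eff := rgamma(.N, shape = 1 / config$nb_dispersion,
                       scale = config$nb_dispersion)]
  bins[, locus_id := NA_integer_]
  bins[, frac := 0]
  for (ch in genome$index$chrom) {
    lc <- locs[chrom == ch]
    if (nrow(lc) == 0L) next
    sel <- which(bins$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(bins$start[sel] + 1L, bins$end[sel]),
      IRanges::IRanges(lc$s + 1L, lc$e))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::IRanges(bins$start[sel][qh] + 1L, bins$end[sel][qh]),
      IRanges::IRanges(lc$s[sh] + 1L, lc$e[sh])))
    bins$locus_id[sel[qh]] <- lc$locus_id[sh]
    bins$frac[sel[qh]] <- w / (bins$end[sel][qh] - bins$start[sel][qh])
  }

  truth <- list(loci = loci[, .(locus_id, chrom, start, end, class,
                                subclass)],
                meth = truth_meth, srna = truth_srna,
                expr = merge(truth_expr,
                             fe[, .(feature_id, kind, base_rate, eff)],
                             by = "feature_id"))
  structure(list(genome = genome,
                 features = feats[, .(chrom, start, end, strand, kind, id)],
                 structural = struct[, .(chrom, start, end)],
                 states = states, truth = truth, cytosines = cyt,
                 srna_bins = bins, config = config),
            class = "rddm_sim")
}

#' @export
print.rddm_sim <- function(x, ...) {
  cat(sprintf(paste0("<rddm_sim> genome %s bp, %d loci ",
                     "(%d RdDM), %d features, %d cytosines\n"),
              format(sum(as.numeric(x$genome$index$length)),
                     big.mark = ","),
              nrow(x$truth$loci),
              sum(x$truth$loci$class == "RdDM"),
              nrow(x$features), nrow(x$cytosines)))
  invisible(x)
}

#' Tile a genome into fixed-width bins
#'
#' @param genome `rddm_genome`.
#' @param bin_size bin width in bp; the terminal bin of each chromosome may
#'   be shorter.
#' @return data.table (chrom, start, end), 0-based half-open.
#' @export
tile_genome <- function(genome, bin_size = 100L) {
  out <- lapply(seq_len(nrow(genome$index)), function(i) {
    L <- genome$index$length[i]
    st <- seq.int(0L, L - 1L, by = bin_size)
    data.table(chrom = genome$index$chrom[i], start = st,
               end = pmin(st + bin_size, L))
  })
  rbindlist(out)
}

#' Simulate a bisulfite methylome for one genotype
#'
#' Per cytosine: the locus/genotype/context methylation level is jittered
#' site-by-site with a Beta(level * c, (1 - level) * c) quantile of a
#' per-site uniform that is SHARED across genotypes (so replicate libraries
#' differ only by counting noise); coverage is Poisson(coverage_mean) and
#' the methylated count Binomial(coverage, site level).
#'
#' @param sim `rddm_sim` world.
#' @param genotype one of the configured genotypes.
#' @param coverage_mean mean per-cytosine coverage (default from config).
#' @param seed seed for the coverage/count draws (site noise stays tied to
#'   the world's own seed).
#' @return CX-style data.table (chrom, pos, strand, context, meth, unmeth,
#'   tri) accepted by [write_cx_report()] and all downstream callers.
#' @export
simulate_methylome <- function(sim, genotype,
                               coverage_mean = sim$config$coverage_mean,
                               seed = sim$config$seed + 1L) {
  if (!genotype %in% sim$config$genotypes)
    .stopf("unknown genotype '%s'", genotype)
  cyt <- sim$cytosines
  gt <- genotype
  lev <- sim$truth$meth[genotype == gt]
  m <- merge(cyt, lev[, .(locus_id, cg, chg, chh)], by = "locus_id",
             all.x = TRUE, sort = FALSE)
  m[, level := fifelse(context == "CG", cg,
                       fifelse(context == "CHG", chg, chh))]
  bg <- sim$config$background_levels
  m[is.na(level), level := fifelse(context == "CG", bg[["cg"]],
                                   fifelse(context == "CHG", bg[["chg"]],
                                           bg[["chh"]]))]
  conc <- sim$config$beta_concentration
  m[, prop := fifelse(level <= 0, 0,
                      fifelse(level >= 1, 1,
                              qbeta(site_u, level * conc,
                                    (1 - level) * conc)))]
  set.seed(seed)
  n <- nrow(m)
  if (coverage_mean <= 0) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth = integer(), unmeth = integer(),
                      tri = character()))
  }
  cov <- rpois(n, coverage_mean)
  meth_ct <- rbinom(n, cov, m$prop)
  out <- m[, .(chrom, pos, strand, context)]
  out[, `:=`(meth = meth_ct, unmeth = cov - meth_ct, tri = m$tri)]
  setorder(out, chrom, pos, strand)
  out[]
}

#' Simulate a 24-nt siRNA library for one genotype
#'
#' Expected bin counts are proportional to the genotype's locus weight
#' (background 1) times a per-bin gamma efficiency shared across genotypes;
#' realised counts are Poisson, so marginally negative binomial with the
#' configured dispersion. Optionally also emits per-read records including
#' non-24-nt reads, structural-RNA reads and multi-mappers to exercise the
#' read filters; the filtered, binned per-read output reproduces `bins`.
#'
#' @param sim `rddm_sim` world.
#' @param genotype genotype name.
#' @param library_size expected total 24-nt reads.
#' @param seed seed for the count draws.
#' @param per_read also emit per-read records (data.table chrom, start,
#'   end, strand, length_nt, multi).
#' @return list: `bins` (chrom, start, end, count — filtered unique 24-nt
#'   reads), `total_mapped` (retained 18-30-nt reads, the RPTM
#'   denominator), `total_24`, and `reads` (or NULL).
#' @export
simulate_srna_library <- function(sim, genotype,
                                  library_size =
                                    sim$config$srna_library_size,
                                  seed = sim$config$seed + 2L,
                                  per_read = FALSE) {
  if (!genotype %in% sim$config$genotypes)
    .stopf("unknown genotype '%s'", genotype)
  if (library_size <= 0) .stopf("library_size must be positive")
  bins <- copy(sim$srna_bins)
  gt <- genotype
  wtab <- sim$truth$srna[genotype == gt]
  bins <- merge(bins, wtab[, .(locus_id, weight)], by = "locus_id",
                all.x = TRUE, sort = FALSE)
  bins[, weight := fifelse(is.na(weight), 1, 1 * (1 - frac) + weight * frac)]
  set.seed(seed)
  mu <- library_size * bins$weight * bins$eff /
    sum(bins$weight * bins$eff)
  bins[, count := rpois(.N, mu)]
  setorder(bins, chrom, start)
  total24 <- sum(bins$count)
  cfg <- sim$config
  n_other <- round(total24 * cfg$srna_other_len_fraction /
                     (1 - cfg$srna_other_len_fraction))
  total_mapped <- total24 + n_other

  reads <- NULL
  if (per_read) {
    lens <- setNames(sim$genome$index$length, sim$genome$index$chrom)
    idx <- rep(seq_len(nrow(bins)), bins$count)
    b <- bins[idx]
    fivep <- b$start + floor(runif(length(idx)) * (b$end - b$start))
    strand24 <- sample(c("+", "-"), length(idx), replace = TRUE)
    st <- fifelse(strand24 == "+", fivep, pmax(0L, fivep - 23L))
    en <- pmin(as.integer(lens[b$chrom]),
               fifelse(strand24 == "+", fivep + 24L, fivep + 1L))
    main <- data.table(chrom = b$chrom, start = st, end = en,
                       strand = strand24, length_nt = 24L, multi = FALSE)
    # the 5' end must stay in the source bin even after clipping
    main[strand24 == "-" & en - st < 24L, start := pmax(0L, end - 24L)]

    rnd_reads <- function(n, len_choices, within = NULL) {
      if (n <= 0) return(NULL)
      ln <- sample(len_choices, n, replace = TRUE)
      if (is.null(within)) {
        ci <- sample(names(lens), n, replace = TRUE)
        st <- floor(runif(n) * (lens[ci] - ln))
      } else {
        wi <- within[sample(nrow(within), n, replace = TRUE)]
        ci <- wi$chrom
        st <- wi$start + floor(runif(n) * pmax(1, wi$end - wi$start - ln))
      }
      data.table(chrom = ci, start = as.integer(st),
                 end = as.integer(st + ln),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 length_nt = ln, multi = FALSE)
    }
    other <- rnd_reads(n_other, c(21L, 22L, 23L, 25L))
    n_struct <- round(total24 * cfg$srna_structural_fraction)
    stru <- if (nrow(sim$structural))
      rnd_reads(n_struct, 24L, within = sim$structural) else NULL
    n_multi <- round(total24 * cfg$srna_multi_fraction)
    mm <- rnd_reads(n_multi, 24L)
    if (!is.null(mm)) mm[, multi := TRUE]
    reads <- rbindlist(list(main, other, stru, mm), use.names = TRUE)
    setorder(reads, chrom, start)
  }
  list(bins = bins[, .(chrom, start, end, count)],
       total_mapped = total_mapped, total_24 = total24, reads = reads)
}

#' Simulate gene/TE expression counts for one genotype
#'
#' Expected counts follow feature base rates times the genotype fold times
#' a per-feature gamma efficiency shared across genotypes; realised counts
#' are Poisson (marginally negative binomial).
#'
#' @param sim `rddm_sim` world.
#' @param genotype genotype name.
#' @param library_size expected total counts.
#' @param seed seed for the draws.
#' @return data.table (id, kind, count).
#' @export
simulate_expression <- function(sim, genotype,
                                library_size = sim$config$expr_library_size,
                                seed = sim$config$seed + 3L) {
  if (!genotype %in% sim$config$genotypes)
    .stopf("unknown genotype '%s'", genotype)
  gt <- genotype
  ex <- sim$truth$expr[genotype == gt]
  set.seed(seed)
  mu <- library_size * ex$base_rate * ex$fold * ex$eff /
    sum(ex$base_rate * ex$eff)
  out <- data.table(id = ex$feature_id, kind = ex$kind,
                    count = rpois(nrow(ex), mu))
  setorder(out, id)
  out[]
}

#' Write all simulation inputs to disk
#'
#' Emits FASTA, GFF3 annotation, chromatin-state BED, structural-RNA mask
#' BED, and the truth tables as TSV.
#'
#' @param sim `rddm_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "features.gff3"),
    states = file.path(dir, "states.bed"),
    mask = file.path(dir, "structural.bed"),
    truth = file.path(dir, "truth_loci.tsv"))
  write_genome_fasta(sim$genome, paths["fasta"])
  write_features_gff3(sim$features, paths["gff"])
  write_states_bed(sim$states, paths["states"])
  fwrite(sim$structural, paths["mask"], sep = "\t", col.names = FALSE)
  fwrite(sim$truth$loci, paths["truth"], sep = "\t")
  invisible(paths)
}
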