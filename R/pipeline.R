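#' Build a pipeline run configuration
#'
#' Single source of all paths and caller parameters, with the defaults
#' used throughout: 100-bp bins, per-site coverage >= 4 in both samples,
#' methylation-difference thresholds mCG 0.4 / mCHG 0.2 / mCHH 0.1, DMR
#' q < 0.05, 200-bp joining, RPTM > 5 retention, DSR FDR 0.01, DEG FDR
#' 0.05 with fold change 2, 1-kb flanks. All randomness flows from the
#' single root seed.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param pairs mutant genotypes compared against WT.
#' @param bin_size,min_cov,thresholds,dmr_q,join_gap DMR parameters.
#' @param rptm_min,dsr_fdr DSR parameters.
#' @param deg_fdr,deg_fc DEG parameters.
#' @param flank flank width for DEG-DMR association and promoters.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("rddmr_run_"), seed = 1L,
                       sim = sim_config(seed = seed),
                       pairs = c("pkl", "nrpd1", "nrpe1"),
                       bin_size = 100L, min_cov = 4L,
                       thresholds = dmr_thresholds, dmr_q = 0.05,
                       join_gap = 200L, rptm_min = 5, dsr_fdr = 0.01,
                       deg_fdr = 0.05, deg_fc = 2, flank = 1000L) {
  stopifnot(bin_size > 0, min_cov >= 0, dmr_q > 0, dmr_q < 1,
            join_gap >= 0, dsr_fdr > 0, dsr_fdr < 1,
            deg_fdr > 0, deg_fdr < 1, deg_fc >= 1, flank >= 0)
  sim$seed <- seed
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-stage seeds below 2^31, all derived from the root seed
.stage_seed <- function(seed, stage, genotype = "") {
  key <- paste(stage, genotype, sep = ":")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 1009L + h * 31L) %% 2000000011L
}

#' Run the full synthetic pipeline
#'
#' simulate -> per-pair DMR calling (three contexts) -> DSR calling ->
#' DEG calling -> feature partition and DMR distribution -> CHH hypoDMR
#' overlap and total-length accounting -> DSR/methylation delta table ->
#' chromatin-state enrichment -> DEG-hypoDMR flank association and
#' promoter methylation. Writes per-stage TSV/BED outputs, a summary
#' table and a machine-readable manifest, all deterministic given the
#' config.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results (`sim`,
#'   `dmrs`, `dsrs`, `degs`, `summary`, paths).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  say("[simulate] building synthetic world (seed %d)", config$seed)
  sim <- simulate_genome(config$sim)
  in_paths <- write_sim_inputs(sim, file.path(config$out_dir, "inputs"))

  genotypes <- unique(c("WT", config$pairs))
  say("[simulate] methylomes: %s", paste(genotypes, collapse = ", "))
  meth <- lapply(setNames(genotypes, genotypes), function(g)
    simulate_methylome(sim, g, seed = .stage_seed(config$seed, "meth", g)))
  say("[simulate] siRNA libraries")
  srna <- lapply(setNames(genotypes, genotypes), function(g) {
    lib <- simulate_srna_library(sim, g,
                                 seed = .stage_seed(config$seed, "srna", g))
    srna_bins(lib$bins, lib$total_mapped)
  })
  expr <- lapply(setNames(genotypes, genotypes), function(g)
    simulate_expression(sim, g, seed = .stage_seed(config$seed, "expr", g)))

  summary_rows <- list()
  add <- function(stage, metric, value)
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.table(stage = stage, metric = metric, value = value)

  dmrs <- list()
  for (g in config$pairs) {
    say("[dmr] WT vs %s", g)
    res <- call_dmr_pipeline(meth$WT, meth[[g]], sim$genome,
                             bin_size = config$bin_size,
                             min_cov = config$min_cov,
                             thresholds = config$thresholds,
                             q_cutoff = config$dmr_q,
                             join_gap = config$join_gap)
    dmrs[[g]] <- res$dmrs
    fwrite(res$bins, file.path(config$out_dir,
                               sprintf("bins_%s.tsv", g)), sep = "\t")
    fwrite(res$dmrs, file.path(config$out_dir,
                               sprintf("dmrs_%s.tsv", g)), sep = "\t")
    write_regions_bed(res$dmrs, file.path(config$out_dir,
                                          sprintf("dmrs_%s.bed", g)))
    for (ctx in unique(res$dmrs$context)) {
      for (dirn in c("hypo", "hyper")) {
        st <- dmr_stats(res$dmrs[context == ctx & direction == dirn])
        add("dmr", sprintf("%s_%s_%s_n", g, ctx, dirn), st$n)
        add("dmr", sprintf("%s_%s_%s_total_bp", g, ctx, dirn),
            st$total_length_bp)
        add("dmr", sprintf("%s_%s_%s_mean_len", g, ctx, dirn),
            st$mean_length)
      }
    }
  }

  dsrs <- list()
  for (g in config$pairs) {
    say("[dsr] WT vs %s", g)
    res <- call_dsrs(srna$WT, srna[[g]], min_rptm = config$rptm_min,
                     fdr = config$dsr_fdr)
    dsrs[[g]] <- res$dsrs
    fwrite(res$dsrs, file.path(config$out_dir,
                               sprintf("dsrs_%s.tsv", g)), sep = "\t")
    add("dsr", sprintf("%s_n", g), nrow(res$dsrs))
    add("dsr", sprintf("%s_down_n", g),
        nrow(res$dsrs[direction == "down"]))
    add("dsr", sprintf("%s_up_n", g), nrow(res$dsrs[direction == "up"]))
  }

  degs <- list()
  for (g in config$pairs) {
    say("[deg] WT vs %s", g)
    cnt <- merge(expr$WT[, .(id, kind, count_wt = count)],
                 expr[[g]][, .(id, count_mut = count)], by = "id")
    degs[[g]] <- call_degs(cnt, fdr = config$deg_fdr, fc = config$deg_fc)
    fwrite(degs[[g]], file.path(config$out_dir,
                                sprintf("degs_%s.tsv", g)), sep = "\t")
    add("deg", sprintf("%s_up_genes", g),
        nrow(degs[[g]][status == "up" & kind == "gene"]))
    add("deg", sprintf("%s_up_tes", g),
        nrow(degs[[g]][status == "up" & kind == "TE"]))
    add("deg", sprintf("%s_down_genes", g),
        nrow(degs[[g]][status == "down" & kind == "gene"]))
  }

  say("[annotate] feature partition and DMR distribution")
  part <- build_partition(sim$features, sim$genome)
  fwrite(part, file.path(config$out_dir, "partition.tsv"), sep = "\t")
  for (g in config$pairs) {
    hypo <- dmrs[[g]][direction == "hypo"]
    if (nrow(hypo)) {
      fr <- distribute_regions(hypo, part)
      for (cl in names(fr))
        add("partition", sprintf("%s_hypo_frac_%s", g, cl),
            round(fr[[cl]], 4))
    }
  }

  # CHH hypoDMR overlap accounting across mutants (RdDM-target logic)
  chh_hypo <- lapply(dmrs, function(d) d[context == "CHH" &
                                           direction == "hypo"])
  if (all(c("pkl", "nrpd1", "nrpe1") %in% names(chh_hypo)) &&
      nrow(chh_hypo$pkl)) {
    rddm_ref <- overlap_union(chh_hypo$nrpd1, chh_hypo$nrpe1)
    ov <- overlap_sets(chh_hypo$pkl, rddm_ref)
    add("overlap", "pkl_chh_hypo_n", nrow(chh_hypo$pkl))
    add("overlap", "pkl_chh_hypo_in_rddm_n", ov$n_a_overlapping_b)
    add("overlap", "pkl_chh_hypo_in_rddm_pct",
        percent_overlap(ov$n_a_overlapping_b, nrow(chh_hypo$pkl)))
    add("overlap", "pkl_chh_total_bp", ov$total_bp_a)
    add("overlap", "rddm_chh_total_bp", ov$total_bp_b)
    add("overlap", "overlap_total_bp", ov$overlap_bp)
    add("overlap", "rddm_len_covered_pct",
        percent_overlap(ov$overlap_bp, ov$total_bp_b, digits = 0))
  }

  say("[delta] DSR siRNA/methylation deltas")
  if ("pkl" %in% names(dsrs) && nrow(dsrs$pkl)) {
    ds <- delta_scatter(dsrs$pkl, srna$WT, srna$pkl, meth$WT, meth$pkl)
    fwrite(ds$table, file.path(config$out_dir, "delta_pkl.tsv"),
           sep = "\t")
    fwrite(ds$correlations,
           file.path(config$out_dir, "delta_pkl_cor.tsv"), sep = "\t")
    sp <- ds$correlations[context == "CHH" & method == "spearman"]
    add("delta", "pkl_chh_spearman", round(sp$estimate, 4))
  }

  say("[enrich] chromatin states")
  for (g in config$pairs) {
    hypo <- dmrs[[g]][context == "CHH" & direction == "hypo"]
    if (nrow(hypo) == 0L) next
    enr <- state_enrichment(hypo, sim$states, sim$genome,
                            unit = config$bin_size)
    fwrite(enr, file.path(config$out_dir,
                          sprintf("state_enrichment_%s.tsv", g)),
           sep = "\t")
    add("enrich", sprintf("%s_state8_fold", g),
        round(enr[state == 8, fold], 3))
    add("enrich", sprintf("%s_state8_neglog10q", g),
        round(enr[state == 8, neg_log10_q], 2))
  }

  say("[flank] DEG-hypoDMR association")
  if ("pkl" %in% names(degs)) {
    up_ids <- degs$pkl[status == "up", id]
    up_feats <- sim$features[id %in% up_ids]
    all_hypo <- dmrs$pkl[direction == "hypo"]
    if (nrow(up_feats) && nrow(all_hypo)) {
      fa <- flank_associate(up_feats, all_hypo, sim$genome,
                            flank = config$flank)
      add("flank", "pkl_up_features_with_hypodmr", fa$n_features)
      add("flank", "pkl_hypodmrs_near_up_features", fa$n_dmrs)
      fwrite(fa$pairs, file.path(config$out_dir, "flank_pairs_pkl.tsv"),
             sep = "\t")
      if (fa$n_features) {
        pm <- promoter_methylation(
          sim$features[id %in% fa$pairs$feature_id],
          list(WT = meth$WT, mut = meth$pkl), flank = config$flank)
        fwrite(pm, file.path(config$out_dir, "promoter_meth_pkl.tsv"),
               sep = "\t")
      }
    }
  }

  summary <- rbindlist(summary_rows)
  fwrite(summary, file.path(config$out_dir, "summary.tsv"), sep = "\t")

  manifest <- list(
    package = "rddmr",
    version = as.character(utils::packageVersion("rddmr")),
    seed = config$seed,
    parameters = config[c("bin_size", "min_cov", "dmr_q", "join_gap",
                          "rptm_min", "dsr_fdr", "deg_fdr", "deg_fc",
                          "flank")],
    thresholds = as.list(config$thresholds),
    sim = config$sim[c("genome_size", "n_chroms", "n_rddm_loci",
                       "n_het_loci", "n_genes", "coverage_mean",
                       "srna_library_size", "pkl_delta_chh")],
    genotype_pairs = config$pairs,
    input_md5 = as.list(tools::md5sum(unname(in_paths))),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 1))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[done] %s", config$out_dir)
  invisible(list(sim = sim, meth = meth, srna = srna, expr = expr,
                 dmrs = dmrs, dsrs = dsrs, degs = degs,
                 partition = part, summary = summary,
                 out_dir = config$out_dir))
}

#' Merged union of two region sets
#'
#' @param a,b data.tables (chrom, start, end).
#' @return merged data.table (chrom, start, end).
#' @export
overlap_union <- function(a, b) {
  ab <- rbind(as.data.table(a)[, .(chrom, start, end)],
              as.data.table(b)[, .(chrom, start, end)])
  chroms <- unique(ab$chrom)
  .irl_dt(IRanges::reduce(.irl(ab, chroms)))
}

#' Export a heatmap-ready methylation matrix over regions
#'
#' Rows are regions (sorted by coordinates), columns are sample x context
#' pooled methylation levels.
#'
#' @param regions data.table (chrom, start, end).
#' @param cx_samples named list of CX-style cytosine tables.
#' @param contexts contexts to include.
#' @return numeric matrix with `chrom:start-end` rownames; NA where a
#'   region has no covered cytosine of that context.
#' @export
export_meth_matrix <- function(regions, cx_samples,
                               contexts = c("CG", "CHG", "CHH")) {
  regions <- .check_regions(as.data.table(regions))
  setorder(regions, chrom, start, end)
  rn <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  cols <- as.vector(outer(names(cx_samples), contexts, paste, sep = "_"))
  mat <- matrix(NA_real_, nrow = nrow(regions), ncol = length(cols),
                dimnames = list(rn, cols))
  if (nrow(regions) == 0L) return(mat)
  regions <- copy(regions)[, feature_id := .I]
  for (sn in names(cx_samples)) {
    cx <- as.data.table(cx_samples[[sn]])
    chroms <- unique(c(regions$chrom, cx$chrom))
    cxiv <- data.table(chrom = cx$chrom, start = cx$pos, end = cx$pos + 1L)
    hits <- IRanges::findOverlaps(.irl(regions, chroms),
                                  .irl(cxiv, chroms))
    rows <- rbindlist(lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (length(h) == 0L) return(NULL)
      ridx <- which(regions$chrom == chroms[i])[S4Vectors::queryHits(h)]
      cidx <- which(cx$chrom == chroms[i])[S4Vectors::subjectHits(h)]
      data.table(feature_id = regions$feature_id[ridx],
                 context = cx$context[cidx],
                 meth = cx$meth[cidx], unmeth = cx$unmeth[cidx])
    }))
    if (is.null(rows) || nrow(rows) == 0L) next
    lv <- rows[, .(meth = sum(meth), unmeth = sum(unmeth)),
               by = .(feature_id, context)]
    lv <- lv[meth + unmeth > 0]
    for (ctx in contexts) {
      sub <- lv[context == ctx]
      mat[sub$feature_id, paste(sn, ctx, sep = "_")] <-
        sub$meth / (sub$meth + sub$unmeth)
    }
  }
  mat
}
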