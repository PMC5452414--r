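# Desk-scale synthetic world shared across test files. Cached so the
# generator runs once per test session.
tiny_cfg <- function(...) {
  defaults <- list(genome_size = 150000, n_rddm_loci = 20, n_het_loci = 8,
                   n_genes = 15, n_structural = 4, n_te_derepressed = 5,
                   n_deg_up = 4, n_deg_down = 4, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.world_cache <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(.world_cache$sim)) .world_cache$sim <-
      simulate_genome(tiny_cfg())
  .world_cache$sim
}

# region-level recovery against planted loci: a locus counts as recovered
# when >= cover_frac of its length is covered by called regions of the
# matching direction; a called region is a true positive when >=
# cover_frac of its length lies inside matching planted loci.
recovery_stats <- function(called, truth_loci, cover_frac = 0.5) {
  cov_frac_of <- function(x, y) {
    # per-row fraction of x covered by the merged set y
    if (nrow(x) == 0L) return(numeric())
    vapply(seq_len(nrow(x)), function(i) {
      xi <- x[i]
      ov <- overlap_sets(xi, y)
      ov$overlap_bp / (xi$end - xi$start)
    }, 0)
  }
  sens_num <- 0L
  for (dirn in unique(truth_loci$direction)) {
    tl <- truth_loci[truth_loci$direction == dirn]
    cl <- called[called$direction == dirn]
    if (nrow(tl) == 0L) next
    if (nrow(cl) == 0L) next
    sens_num <- sens_num + sum(cov_frac_of(tl, cl) >= cover_frac)
  }
  prec_num <- 0L
  for (dirn in unique(called$direction)) {
    cl <- called[called$direction == dirn]
    tl <- truth_loci[truth_loci$direction == dirn]
    if (nrow(cl) == 0L) next
    if (nrow(tl) == 0L) next
    prec_num <- prec_num + sum(cov_frac_of(cl, tl) >= cover_frac)
  }
  list(sensitivity = sens_num / max(1L, nrow(truth_loci)),
       precision = prec_num / max(1L, nrow(called)))
}
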