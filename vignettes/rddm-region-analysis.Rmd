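---
title: "Bin-based DMR/DSR analysis of RdDM mutants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based DMR/DSR analysis of RdDM mutants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmr)
library(data.table)
```

## The problem

In plants, RNA-directed DNA methylation (RdDM) deposits cytosine
methylation — most diagnostically in the CHH context (H = A, C or T) — at
loci targeted by Pol IV-derived 24-nt siRNAs. Chromatin factors such as
the CHD3 remodeler PICKLE (PKL) modulate this pathway: their mutants show
*partial* methylation and siRNA losses at a subset of RdDM loci, in
contrast to *nrpd1* / *nrpe1* (Pol IV / Pol V largest subunits), whose
mutation essentially abolishes CHH methylation and siRNA production at
those loci.

`rddmr` implements the standard count-level analysis for such studies:

1. **DMR calling** from per-cytosine bisulfite counts, in 100-bp bins,
   separately for CG, CHG and CHH;
2. **DSR calling** (differential 24-nt siRNA regions) from RPTM-normalized
   100-bp bin counts;
3. **DEG calling** for genes and TEs from count matrices;
4. **region-set analyses**: genomic feature partition, overlap and
   total-length accounting, DSR siRNA/methylation delta correlation,
   chromatin-state enrichment, DEG–DMR flank association and promoter
   methylation;
5. a **synthetic-data generator** that plants known effects so every stage
   can be scored against ground truth.

## Statistical models

### DMR calling

For each 100-bp bin and context, methylated/unmethylated counts are pooled
over the *informative* cytosines — sites covered at least `min_cov` (4)
times in **both** samples. The two samples' pooled counts form a 2x2 table
tested with Fisher's exact test (two-sided by the point-probability rule:
the p-value sums the probabilities of all tables with the observed margins
that are no more likely than the observed one). Benjamini–Hochberg
adjustment is applied **within each context** over all testable bins. A
bin is significant iff

* |level difference| strictly exceeds the context threshold
  (mCG 0.4, mCHG 0.2, mCHH 0.1), **and**
* q is strictly below 0.05.

Significant bins of the same chromosome, context and direction whose gap
is at most 200 bp are joined into DMRs. Hypo and hyper bins never join;
contexts never join. Terminal short bins at chromosome ends are retained
and testable.

Decisions made where the procedure was genuinely open:

* *"covered at least four times"* is read per cytosine and required in
  both samples; a per-bin reading would let one deep site carry an
  otherwise uncovered bin.
* BH is applied per context because the three context analyses use
  different thresholds and test counts and are reported separately. A
  genome-wide adjustment would couple the three lists for no analytical
  gain.
* Symmetric CG positions are **not** pooled across strands by default
  (nothing in the procedure requires it); `pool_cg_strands = TRUE`
  collapses the minus-strand cytosine onto its plus-strand partner.
* Ties exactly at a cutoff are not significant (strict inequalities).
* A pooled "total C" mode (`pool_contexts = TRUE`, threshold 0.1) is
  exposed but flagged experimental.

### DSR and DEG calling

Bin counts of 24-nt reads are normalized to reads per ten million,
`RPTM = count x 1e7 / total_mapped`, where `total_mapped` counts all
retained 18–30-nt reads (after removing structural-RNA reads and
multi-mappers) and binned counts use 24-nt reads only, assigned to the bin
containing the read's 5' end. Bins with RPTM strictly above 5 in either
sample are retained.

With one library per genotype, a dispersion parameter is not estimable, so
differential testing uses an **exact conditional binomial rate test**:
under equal per-read rates, conditional on the total `x1 + x2`, `x1` is
`Binomial(x1 + x2, n1/(n1 + n2))`; the two-sided p-value again follows the
point-probability rule. The same test drives DEG calling, where a feature
is up/down only if q < 0.05 **and** the library-size-normalized fold
change reaches 2. Adjacent (gap 0) significant bins of one direction merge
into DSRs at FDR 0.01.

This test is exact under Poisson-level counting noise but has no
between-replicate dispersion term: with real biological replicates a
negative-binomial framework (edgeR/DESeq2) is the right tool, and p-values
here should be read as "counting-noise" p-values. This is a deliberate,
documented substitution; the package's acceptance is simulation-based.

### Region-set analyses

All interval algebra is 0-based half-open internally and delegates to
IRanges; conversions happen only at file boundaries (CX reports and GFF3
are 1-based). The feature partition assigns every bp to exactly one of
gene / TE / gene-TE / intergenic and provably tiles the genome; region
distributions are bp-weighted by default (a majority-class mode exists)
because a bp measure stays well defined for regions straddling classes.
Reported percentages round half-up (91.65 -> 91.7), matching the usual
reporting convention.

Chromatin-state enrichment compares observed overlap bp with the
expectation under uniform placement and computes a one-sided binomial
p-value on 100-bp units (n = region bp / 100, success probability = the
state's genome fraction), BH-adjusted over the nine states. The unit size
matches the bin width the regions were built from, which is the natural
independence scale of bin-derived regions; a seeded within-chromosome
permutation mode is provided as a model-free cross-check.

## The synthetic world

The generator emulates a small Arabidopsis-like genome (default 2 Mb, one
chromosome, uniform base composition) with non-overlapping planted loci:

* **200 RdDM loci** (300–800 bp): WT CHH ~ U(0.1, 0.4), CHG ~ U(0.2,
  0.6), CG ~ U(0.75, 0.85); high siRNA weight (40x background).
* **pkl**: a configurable half of the RdDM loci lose exactly
  `pkl_delta_chh = 0.3` of CHH (their WT level is drawn from
  U(0.32, 0.40) so the planted drop leaves a partial residual — the only
  way to honor both the 0.1–0.4 band and a fixed 0.3 effect), with milder
  CHG/CG reductions and a 5-fold siRNA drop; a disjoint 10% subset starts
  low (U(0.02, 0.05)) and gains 0.3 CHH with a 5-fold siRNA gain.
* **nrpd1 / nrpe1**: CHH collapses to a basal 0.02 and CHG to 0.05 at
  every RdDM locus; siRNA to background in *nrpd1*, 4-fold down in
  *nrpe1*.
* **100 heterochromatic loci** (high CG/CHG, moderate CHH, genotype
  stable), **300 genes** (low gene-body CG), **20 structural-RNA loci**,
  and a nine-state chromatin segmentation in which planted loci are
  predominantly state 8.

Counting noise is layered as in real libraries but with one crucial
design choice: the *between-site* and *between-bin* heterogeneity is
drawn **once per world and shared across genotypes**.

* Methylomes: per cytosine, coverage ~ Poisson(20); the methylated count
  is Binomial(coverage, site level) where the site level is the
  Beta(level x c, (1 - level) x c) quantile (c = 50) of a per-site
  uniform stored in the world. Marginally each site is Beta-binomial;
  between two libraries of the *same* genotype only the binomial noise
  differs.
* siRNA bins: expected counts are proportional to locus weight times a
  per-bin gamma efficiency (shape 1/0.2), realised as Poisson — marginally
  negative binomial with dispersion 0.2, but WT-vs-WT contrasts are pure
  Poisson.
* Expression: the same gamma-Poisson construction per feature, with 25
  TEs derepressed 10-fold and 30 genes up / 30 down 4-fold in *pkl*.

This choice is what makes the null controls meaningful: a WT-vs-WT
replicate comparison is a *true* null for the exact conditional tests, so
the empirical false-positive rate can be compared to the nominal level.
What a green test therefore establishes: the callers recover planted
region-level effects of the stated size at the stated coverage and hold
their nominal error rates under counting noise. What it does not
establish: behavior under between-replicate biological dispersion,
alignment/conversion artifacts, non-uniform genome composition or
mappability structure — none of which the generator emulates.

A note on the DSR precision numbers: at FDR 0.01 over ~20,000 retained
bins with ~1,200 truly changed bins, about 1% of rejections are expected
to be false — region-level precision ~0.92–0.95 is the designed behavior
of FDR control, not a caller defect.

## Numerical choices and degenerate inputs

* Exact-test tie detection uses a 1e-7 relative tolerance when comparing
  point probabilities (the same guard `fisher.test` uses), so
  floating-point noise cannot drop tied tables.
* q-values are capped at 1; `bh_adjust` of a constant vector is that
  constant; empty p-vectors are an error.
* All-zero 2x2 tables and `x1 + x2 = 0` are errors — callers pre-filter
  untestable rows (zero-total features are reported with NA status).
* Zero-coverage CX rows are retained on input; they simply never become
  informative.
* An N in a trinucleotide suppresses the context call; a terminal CG
  dinucleotide is still classifiable (CG needs only two bases).
* DSR logFC uses a 0.5-count pseudocount; display matrices use
  log10(RPTM + 1). Tests always use raw counts.
* Percent reporting rounds half away from zero (`round_half_up`), not
  banker's rounding.
* Regions with no covered cytosine of a context are flagged NA and
  excluded from that context's correlation; correlations additionally
  require n >= 3 and non-zero variance.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
res$summary[stage == "overlap"]
```

`run_pipeline()` writes per-stage TSV/BED outputs plus `summary.tsv` and
`manifest.json` (parameters, seeds, input checksums); a rerun with the
same seed reproduces every output byte for byte. The same stages are
available as CLI subcommands (`simulate`, `dmr`, `dsr`, `deg`,
`run-all`) via `inst/cli/rddm`.

## Known limitations

* One library per genotype; no dispersion estimation, no replicate
  designs.
* The DMR caller is the bin/threshold/join procedure only — no smoothing
  or HMM callers.
* The chromatin-state segmentation is an input (or simulated); it is
  never learned.
* Alignment, trimming and read-level bisulfite conversion are out of
  scope; the pipeline starts from count-level inputs.
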