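#' @importFrom data.table data.table as.data.table setDT setkey setkeyv
#'   setorder setorderv := .N .SD fread fwrite copy rbindlist shift setnames
#'   setattr setcolorder first last fifelse foverlaps
#' @importFrom stats dbinom pbinom rbinom dhyper qbeta rpois runif rgamma
#'   rlnorm cor cor.test setNames complete.cases
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "strand", "context", "meth", "unmeth", "cov_wt",
  "cov_mut", "meth_wt", "unmeth_wt", "meth_mut", "unmeth_mut", "bin",
  "start", "end", "level_wt", "level_mut", "diff_level", "p", "q",
  "significant", "direction", "n_sites", "grp", "count", "rptm",
  "count_wt", "count_mut", "rptm_wt", "rptm_mut", "locus_id", "class",
  "state", "kind", "id", "width", "length_nt", "multi", "name", "score",
  "tri", "level", "chrom_f", "gap", "n_bins", "mean_diff", "min_q",
  "weight", "eff", "fold", "status", "site_u", "feature_id", "sample_id",
  "value", "dlog_rptm", "subclass", "cg", "chg", "chh", "frac", "prop",
  "base_rate", "genotype", "V1", ".I", "..genotype", "s", "e"
))

`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    .stopf("%s must be non-negative integers", what)
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; reported percentages here follow
#' the conventional half-up rule instead (0.45 -> 0.5 at one digit).
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# data.frame/data.table of 0-based half-open intervals -> IRangesList keyed
# by chromosome.  Internal interval algebra runs on IRanges; the +1 shift
# happens here and only here.
.irl <- function(df, chroms = NULL) {
  df <- as.data.table(df)
  if (is.null(chroms)) chroms <- unique(df$chrom)
  # an empty df still yields one (empty) element per chromosome so that
  # elementwise set operations stay aligned
  sp <- split(IRanges::IRanges(start = df$start + 1L, end = df$end),
              factor(df$chrom, levels = chroms))
  methods::as(sp, "IRangesList")
}

# IRangesList -> 0-based half-open data.table
.irl_dt <- function(irl) {
  if (length(irl) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  ul <- unlist(irl, use.names = FALSE)
  data.table(
    chrom = rep(names(irl), lengths(irl)),
    start = BiocGenerics::start(ul) - 1L,
    end   = BiocGenerics::end(ul)
  )
}

.total_bp <- function(irl) sum(sum(IRanges::width(IRanges::reduce(irl))))

.genome_irl <- function(genome) {
  idx <- genome$index
  sp <- split(IRanges::IRanges(start = 1L, end = idx$length),
              factor(idx$chrom, levels = idx$chrom))
  methods::as(sp, "IRangesList")
}

.check_regions <- function(df, what = "regions") {
  df <- as.data.table(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("%s must have columns chrom, start, end", what)
  if (nrow(df) && any(df$end <= df$start))
    .stopf("%s contains intervals with end <= start", what)
  df
}
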