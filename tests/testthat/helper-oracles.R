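# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the distribution functions) used by the package.

# Fisher 2x2: enumerate every table with the observed margins using
# binomial coefficients only.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(N, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(N, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# conditional binomial: enumerate outcome probabilities from first
# principles (log-space binomial coefficients).
oracle_cond_binom <- function(x1, x2, n1, n2) {
  n <- x1 + x2
  pr <- n1 / (n1 + n2)
  lp <- lchoose(n, 0:n) + (0:n) * log(pr) + (n - (0:n)) * log1p(-pr)
  probs <- exp(lp)
  min(1, sum(probs[probs <= probs[x1 + 1] * (1 + 1e-7)]))
}

# BH step-up applied literally to the sorted vector.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, 0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# bin joining by transitive closure over an explicit adjacency graph
# (quadratic; independent of the single-pass stream in call_dmrs).
oracle_merge_bins <- function(starts, ends, join_gap) {
  n <- length(starts)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
    adj[i, j] <- gap <= join_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc)
    data.frame(start = min(starts[comp == cc]),
               end = max(ends[comp == cc]))))
  out[order(out$start), , drop = FALSE]
}

# per-bp bitmap implementations of the interval operations (genome one
# chromosome of length L)
bitmap <- function(df, L) {
  v <- logical(L)
  for (i in seq_len(nrow(df)))
    if (df$end[i] > df$start[i]) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}
bitmap_overlap_bp <- function(a, b, L) sum(bitmap(a, L) & bitmap(b, L))
bitmap_partition <- function(genes, tes, L) {
  g <- bitmap(genes, L); t <- bitmap(tes, L)
  c(gene = sum(g & !t), TE = sum(t & !g), `gene/TE` = sum(g & t),
    intergenic = sum(!g & !t))
}

rand_regions <- function(n, L, max_len = 50L) {
  st <- sample.int(L - max_len, n, replace = TRUE) - 1L
  data.table::data.table(chrom = "chr1", start = st,
                         end = st + sample.int(max_len, n, replace = TRUE))
}
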