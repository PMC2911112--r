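# Independent brute-force oracles used to check the implementation.
# Each is written from the defining formula, not from the package code.

# Step-up FDR by the literal min-over-tails definition:
# q_i = min_{j: p_(j) >= p_i} m * p_(j) / j, clipped to 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q <- vapply(seq_len(m), function(i) {
    js <- which(p_sorted >= p_sorted[i] - 1e-15)
    min(1, min(m * p_sorted[js] / js))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Running-sum enrichment score by an explicit step-by-step walk.
gsea_oracle <- function(metric, is_hit, weight_p) {
  n <- length(metric)
  n_h <- sum(is_hit)
  n_r <- sum(abs(metric[is_hit])^weight_p)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      running <- running + if (n_r > 0) abs(metric[i])^weight_p / n_r else 1 / n_h
    } else {
      running <- running - 1 / (n - n_h)
    }
    # earliest extremum wins magnitude ties (same convention, tolerance 1e-12)
    if (abs(running) > abs(best) + 1e-12) best <- running
  }
  best
}

# Disorder score as the cardinality of the union of residue sets.
residue_union_oracle <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  residues <- unlist(mapply(seq, intervals$start, intervals$end,
                            SIMPLIFY = FALSE))
  length(unique(residues))
}

# Exhaustive same-sign null for n <= 8: enumerate every sign assignment of
# n iid pairs, weighting by the per-pair sign probabilities.
same_sign_tail_enumeration <- function(fx, fy, n, k) {
  q <- fx * fy + (1 - fx) * (1 - fy)
  total <- 0
  for (count in 0:n) {
    if (count >= k) total <- total + choose(n, count) * q^count * (1 - q)^(n - count)
  }
  total
}

# Random expression fixture: probesets x replicates matrices for two groups.
random_groups <- function(n_probes, n_a = 3L, n_b = 3L, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_probes))
    a <- matrix(rnorm(n_probes * n_a, 8, 1), n_probes,
                dimnames = list(ids, paste0("a", seq_len(n_a))))
    b <- matrix(rnorm(n_probes * n_b, 8, 1), n_probes,
                dimnames = list(ids, paste0("b", seq_len(n_b))))
    list(a = a, b = b)
  })
}
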