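#' Rank probesets by basal expression
#'
#' The basal expression of a probeset is its mean normalized log2 intensity
#' across all arrays of the study; the per-probeset standard deviation is
#' attached. The profile is sorted from the most to the least expressed,
#' with ties broken lexicographically by id for reproducibility.
#'
#' @param expr Expression matrix (probesets x samples).
#' @return A data frame with columns `id`, `metric` (mean expression), `sd`,
#'   sorted by decreasing `metric`.
#' @export
basal_ranking <- function(expr) {
  validate_expression_matrix(expr)
  if (ncol(expr) == 0L || nrow(expr) == 0L) stop("empty expression matrix")
  m <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  ord <- order(-m, names(m))
  data.frame(id = names(m)[ord], metric = unname(m[ord]), sd = unname(s[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Running-sum enrichment score of a gene set in a ranked profile
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: walking the ranked
#' list from top to bottom, a set member ("hit") at position i adds
#' `|metric_i|^p / N_R` (with `N_R` the sum of `|metric|^p` over all
#' members), a non-member adds `-1 / (N - N_H)`. The enrichment score is the
#' running-sum deviation of maximum magnitude, in `[-1, 1]`. With
#' `weight_p = 0` this is the classical KS statistic between the hit and
#' miss positions. When the largest positive and largest negative deviations
#' tie in magnitude (to within 1e-12), the earlier extremum along the list
#' is reported.
#'
#' @param profile A [basal_ranking()] data frame (columns `id`, `metric`).
#' @param set Character vector of member ids; must intersect the profile and
#'   must not cover it entirely.
#' @param weight_p Metric weighting exponent (default 1).
#' @return The enrichment score, a single number in `[-1, 1]`.
#' @export
gsea_enrichment_score <- function(profile, set, weight_p = 1) {
  hit <- profile$id %in% set
  n <- length(hit)
  n_h <- sum(hit)
  if (n_h == 0L) stop("gene set does not intersect the ranked profile")
  if (n_h == n) stop("gene set covers the entire profile (miss weight undefined)")
  w <- abs(profile$metric)^weight_p
  n_r <- sum(w[hit])
  increments <- ifelse(hit,
                       if (n_r > 0) w / n_r else 1 / n_h,
                       -1 / (n - n_h))
  if (n_r == 0) increments[!hit] <- -1 / (n - n_h)
  running <- cumsum(increments)
  running[which(abs(running) > max(abs(running)) - 1e-12)[1L]]
}

#' Significance of an enrichment score by set permutation
#'
#' The null distribution is generated by drawing random sets of the same
#' size from the ranked profile (set permutation on a fixed ranking). The
#' p-value uses the add-one counting rule
#' `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`; the q-value uses the
#' sign-stratified normalization of the standard enrichment method: observed
#' and null scores are divided by the mean null magnitude of matching sign
#' and the tail frequency of the normalized null at the observed normalized
#' score is reported.
#'
#' @param profile A [basal_ranking()] data frame.
#' @param set Character vector of member ids.
#' @param weight_p Metric weighting exponent.
#' @param n_perm Number of random sets (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @return A list with `es`, `nes`, `p_value`, `q_value`, `null_es`.
#' @export
gsea_significance <- function(profile, set, weight_p = 1, n_perm = 1000L,
                              seed = 1L) {
  if (n_perm < 100L) stop("gsea_significance: n_perm must be >= 100")
  es <- gsea_enrichment_score(profile, set, weight_p)
  n_h <- sum(profile$id %in% set)
  if (n_h > nrow(profile) / 2) {
    warning("set larger than half the profile: permutation null poorly calibrated")
  }
  null_es <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      rnd <- sample(profile$id, n_h)
      gsea_enrichment_score(profile, rnd, weight_p)
    }, numeric(1L))
  })
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same_sign) == 0L) {
    nes <- NA_real_
    q <- 0
  } else {
    denom <- mean(abs(same_sign))
    nes <- es / denom
    q <- sum(abs(same_sign) / denom >= abs(nes)) / length(same_sign)
  }
  list(es = es, nes = nes, p_value = p, q_value = q, null_es = null_es)
}

#' Total disordered residues of a protein
#'
#' Sums the lengths of the disordered regions after merging overlapping
#' intervals, i.e. the number of distinct residues falling in any
#' disordered region. Coordinates are 1-based inclusive.
#'
#' @param intervals Data frame (or matrix) with columns `start`, `end`; zero
#'   rows give a score of 0.
#' @return Integer disorder score.
#' @export
disorder_score <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) return(0L)
  start <- as.integer(intervals$start)
  end <- as.integer(intervals$end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer interval bounds")
  if (any(start < 1L)) stop("intervals must start at residue >= 1")
  if (any(start > end)) stop("interval with start > end")
  merged <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  as.integer(sum(IRanges::width(merged)))
}

#' Disorder scores for every gene of an interval table
#'
#' @param intervals Data frame with columns `gene`, `start`, `end`.
#' @param genes Optional gene universe; genes without intervals score 0.
#' @return Named integer vector of disorder scores.
#' @export
disorder_scores <- function(intervals, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(intervals$gene))
  vapply(genes, function(g) {
    disorder_score(intervals[intervals$gene == g, , drop = FALSE])
  }, integer(1L))
}

#' Threshold classification of dosage sensitivity from disorder
#'
#' Predicts a gene as effective (dosage-sensitive) when its disorder score
#' reaches the threshold, silent otherwise; disorder-rich proteins are the
#' dosage-sensitive ones. Exceptions are genes whose prediction disagrees
#' with the observed effective/silent label.
#'
#' @param scores Named numeric vector of disorder scores.
#' @param labels Named character vector of observed labels
#'   (`"effective"`/`"silent"`), same genes as `scores`.
#' @param threshold Disorder threshold in residues (default 180).
#' @param exclude Genes to drop before classifying (e.g. clones carrying
#'   non-murine coding sequences).
#' @return A data frame with columns `gene`, `score`, `label`, `predicted`,
#'   `exception`; attribute `exceptions` holds the exception gene names.
#' @export
classify_dosage <- function(scores, labels, threshold = 180,
                            exclude = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  genes <- intersect(names(scores), names(labels))
  genes <- setdiff(genes, exclude)
  if (length(genes) == 0L) stop("no genes to classify")
  out <- data.frame(gene = genes,
                    score = unname(scores[genes]),
                    label = unname(labels[genes]),
                    stringsAsFactors = FALSE)
  out$predicted <- ifelse(out$score >= threshold, "effective", "silent")
  out$exception <- out$predicted != out$label
  attr(out, "exceptions") <- out$gene[out$exception]
  out
}

#' Two-sample t-test comparing disorder scores between label groups
#'
#' Compares effective vs silent disorder scores with a two-sided two-sample
#' t-test (Student's equal-variance by default; `var_equal = FALSE` gives
#' Welch).
#'
#' @param scores Named numeric vector of disorder scores.
#' @param labels Named character labels (`"effective"`/`"silent"`).
#' @param var_equal Use the pooled-variance Student t (default) or Welch.
#' @return A list with `t_stat` (effective minus silent direction),
#'   `p_value`, `df`.
#' @export
disorder_group_test <- function(scores, labels, var_equal = TRUE) {
  genes <- intersect(names(scores), names(labels))
  eff <- scores[genes[labels[genes] == "effective"]]
  sil <- scores[genes[labels[genes] == "silent"]]
  if (length(eff) < 2L || length(sil) < 2L) {
    stop("disorder_group_test: need >= 2 genes per group")
  }
  tt <- stats::t.test(eff, sil, var.equal = var_equal)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
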