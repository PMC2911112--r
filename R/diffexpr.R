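#' Parameters of the regularized t-statistic
#'
#' The regularized (Bayesian-style) t shares variance information across
#' probesets of similar expression: each probeset's sample variance is
#' shrunk toward a background variance estimated from a window of probesets
#' neighbouring it in mean-expression rank.
#'
#' @param window_size Odd window width `w` (>= 3): number of rank-neighbour
#'   probesets over which the background variance is averaged. Windows are
#'   truncated at the ends of the ranking (no wrap-around).
#' @param prior_k Prior confidence `K` (>= 0): pseudo-observations assigned
#'   to the background variance in the shrinkage. `K = 0` recovers the
#'   classical Student t exactly.
#' @return A list of class `reg_t_params`.
#' @export
reg_t_params <- function(window_size = 101L, prior_k = 10) {
  w <- as.integer(window_size)
  if (is.na(w) || w < 3L || w %% 2L == 0L) {
    stop("window_size must be an odd integer >= 3")
  }
  if (prior_k < 0) stop("prior_k must be >= 0")
  structure(list(window_size = w, prior_k = prior_k), class = "reg_t_params")
}

# Background variance per probeset: mean of the sample variances over the
# window of probesets nearest in mean-expression rank (ties broken by id,
# windows truncated at the list ends).
background_variance <- function(group_mean, group_var, window_size) {
  n <- length(group_mean)
  w <- min(window_size, n)
  h <- (w - 1L) %/% 2L
  ord <- order(group_mean, names(group_mean), decreasing = FALSE)
  v_ord <- group_var[ord]
  cs <- c(0, cumsum(v_ord))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  bg_ord <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  bg <- numeric(n)
  bg[ord] <- bg_ord
  names(bg) <- names(group_mean)
  bg
}

#' Regularized two-sample t-statistic per probeset
#'
#' For each group, the per-probeset sample variance `s^2` (on `n - 1`
#' degrees of freedom) is combined with a background variance `sigma0^2`
#' (the mean sample variance over the `window_size` probesets nearest in
#' mean-expression rank) weighted by `K` pseudo-observations:
#'
#' \deqn{\tilde s^2 = \frac{K \sigma_0^2 + (n - 1) s^2}{K + n - 1}}
#'
#' The statistic is `t = (mean_a - mean_b) / sqrt(s~_a^2/n_a + s~_b^2/n_b)`
#' with two-sided p-values from a Student t distribution on
#' `n_a + n_b - 2 + 2K` degrees of freedom (the background contributes `K`
#' pseudo-degrees per group). At `K = 0` both the variance and the degrees
#' of freedom reduce to the classical two-sample t.
#'
#' @param group_a,group_b Numeric matrices (probesets x replicates) sharing
#'   rownames, >= 2 replicates each.
#' @param params A [reg_t_params()].
#' @return A data frame with columns `probeset`, `mean_a`, `mean_b`,
#'   `t_stat`, `p_value`. With `K = 0` and zero total variance the statistic
#'   is undefined and reported as `NA`.
#' @export
regularized_t <- function(group_a, group_b, params = reg_t_params()) {
  stopifnot(inherits(params, "reg_t_params"))
  if (!is.matrix(group_a) || !is.matrix(group_b)) {
    stop("group_a and group_b must be matrices (probesets x replicates)")
  }
  if (is.null(rownames(group_a)) || !identical(rownames(group_a),
                                               rownames(group_b))) {
    stop("groups must share an identical probeset index")
  }
  n_a <- ncol(group_a)
  n_b <- ncol(group_b)
  if (n_a < 2L || n_b < 2L) stop("need >= 2 replicates per group")

  K <- params$prior_k
  m_a <- rowMeans(group_a)
  m_b <- rowMeans(group_b)
  v_a <- apply(group_a, 1L, stats::var)
  v_b <- apply(group_b, 1L, stats::var)

  if (K > 0) {
    bg_a <- background_variance(m_a, v_a, params$window_size)
    bg_b <- background_variance(m_b, v_b, params$window_size)
    s_a <- (K * bg_a + (n_a - 1) * v_a) / (K + n_a - 1)
    s_b <- (K * bg_b + (n_b - 1) * v_b) / (K + n_b - 1)
  } else {
    s_a <- v_a
    s_b <- v_b
  }

  se <- sqrt(s_a / n_a + s_b / n_b)
  t_stat <- (m_a - m_b) / se
  t_stat[se == 0 & m_a == m_b] <- 0
  t_stat[se == 0 & m_a != m_b] <- NA_real_  # undefined at K = 0, zero variance
  df <- n_a + n_b - 2 + 2 * K
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  data.frame(probeset = rownames(group_a), mean_a = m_a, mean_b = m_b,
             t_stat = unname(t_stat), p_value = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j`,
#' clipped to 1. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`, no missing values.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("bh_fdr: missing p-values")
  if (any(p < 0 | p > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for one overexpression experiment
#'
#' Pools the clones of `gene` within each condition (induced vs uninduced),
#' applies the regularized t per probeset and BH FDR across probesets.
#'
#' @param expr Expression matrix (probesets x samples, log2 scale).
#' @param samples Sample annotation data frame (see
#'   [read_sample_annotation()]).
#' @param gene Experiment gene to test.
#' @param params A [reg_t_params()].
#' @param alpha FDR threshold stored with the table (default 0.05; 0.01
#'   reproduces the stricter filtering mode).
#' @param conditions Length-2 character: the test and the reference
#'   condition (default induced vs uninduced; `c("trisomic", "control")`
#'   for the trisomic comparison).
#' @return A data frame of class `de_table` with columns `probeset`,
#'   `mean_induced`, `mean_uninduced`, `log2_fold_change`, `t_stat`,
#'   `p_value`, `q_value`, `significant`; attributes `gene` and `alpha`.
#' @export
run_de <- function(expr, samples, gene, params = reg_t_params(),
                   alpha = 0.05, conditions = c("induced", "uninduced")) {
  check_annotation(expr, samples)
  stopifnot(length(conditions) == 2L)
  ind <- samples$sample_id[samples$experiment_gene == gene &
                             samples$condition == conditions[1L]]
  uni <- samples$sample_id[samples$experiment_gene == gene &
                             samples$condition == conditions[2L]]
  if (length(ind) < 2L || length(uni) < 2L) {
    stop("run_de: need >= 2 '", conditions[1L], "' and >= 2 '",
         conditions[2L], "' samples for ", gene)
  }
  res <- regularized_t(expr[, ind, drop = FALSE], expr[, uni, drop = FALSE],
                       params)
  out <- data.frame(probeset = res$probeset,
                    mean_induced = res$mean_a,
                    mean_uninduced = res$mean_b,
                    log2_fold_change = res$mean_a - res$mean_b,
                    t_stat = res$t_stat,
                    p_value = res$p_value,
                    stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < alpha
  attr(out, "gene") <- gene
  attr(out, "alpha") <- alpha
  class(out) <- c("de_table", class(out))
  out
}

#' Classify overexpressed genes as effective or silent
#'
#' A gene is effective when its experiment yields at least `min_hits`
#' probesets significant at FDR < `alpha`. The gene's own transgene reporter
#' probeset is excluded from the count when `transgene_map` is supplied:
#' induction always up-regulates the reporter itself, and the effective call
#' concerns perturbation of the rest of the transcriptome. The default
#' `min_hits = 5` asks for a small but non-trivial downstream signature:
#' with a single-probeset criterion the false-discovery control per
#' experiment still leaves a non-negligible chance of one stray significant
#' probeset, whereas genuinely effective genes perturb tens to thousands of
#' probesets.
#'
#' @param de_tables Named list of [run_de()] tables, one per gene.
#' @param alpha FDR threshold for counting significant probesets.
#' @param min_hits Minimum number of significant probesets (default 5).
#' @param transgene_map Optional named character vector, gene -> its own
#'   transgene probeset id, excluded from the count.
#' @return A data frame with columns `gene`, `n_significant`, `label`.
#' @export
classify_effective <- function(de_tables, alpha = 0.05, min_hits = 5L,
                               transgene_map = NULL) {
  stopifnot(is.list(de_tables), !is.null(names(de_tables)))
  res <- lapply(names(de_tables), function(g) {
    tab <- de_tables[[g]]
    keep <- rep(TRUE, nrow(tab))
    if (!is.null(transgene_map) && g %in% names(transgene_map)) {
      keep <- tab$probeset != transgene_map[[g]]
    }
    n_sig <- sum(tab$q_value[keep] < alpha, na.rm = TRUE)
    data.frame(gene = g, n_significant = n_sig,
               label = if (n_sig >= min_hits) "effective" else "silent",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test transgene leakiness in the uninduced state
#'
#' For every gene, compares the expression of its own transgene reporter
#' probeset between the parental cell line samples and the gene's uninduced
#' clone samples with a classical two-sample Student t-test, then adjusts
#' across genes with BH FDR. A gene is leaky when q < `alpha`.
#'
#' @param expr Expression matrix including parental samples.
#' @param samples Sample annotation; must contain `condition == "parental"`.
#' @param transgene_map Named character vector, gene -> reporter probeset.
#' @param alpha FDR threshold for the leaky call.
#' @return A data frame with columns `gene`, `t_stat`, `p_value`, `q_value`,
#'   `leaky`.
#' @export
leakiness_test <- function(expr, samples, transgene_map, alpha = 0.05) {
  check_annotation(expr, samples)
  parental <- samples$sample_id[samples$condition == "parental"]
  if (length(parental) < 2L) {
    stop("leakiness_test: need >= 2 parental samples")
  }
  genes <- names(transgene_map)
  res <- lapply(genes, function(g) {
    uni <- samples$sample_id[samples$experiment_gene == g &
                               samples$condition == "uninduced"]
    if (length(uni) < 2L) {
      stop("leakiness_test: need >= 2 uninduced samples for ", g)
    }
    x <- expr[transgene_map[[g]], uni]
    y <- expr[transgene_map[[g]], parental]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(gene = g, t_stat = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out$leaky <- out$q_value < alpha
  rownames(out) <- NULL
  out
}

#' Relative expression from comparative Ct values
#'
#' The comparative Ct quantification: `2^-(ct_target - ct_reference)`,
#' expression of a target relative to a housekeeping reference.
#'
#' @param ct_target,ct_reference Finite Ct values (vectors recycle).
#' @return `2^-(ct_target - ct_reference)`.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference))) {
    stop("relative_expression: Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}
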