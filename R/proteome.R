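#' Percent-volume normalization of a spot table
#'
#' Expresses each spot's intensity as a percentage of the total spot volume
#' of its parent gel: per gel (column), `value <- 100 * value / sum(values)`.
#' Scale-invariant per gel and idempotent up to the constant total.
#'
#' @param volumes Non-negative matrix, spots x gels; every gel total > 0.
#' @return Matrix of percent volumes; each column sums to 100.
#' @export
percent_volume <- function(volumes) {
  if (!is.matrix(volumes) || !is.numeric(volumes)) {
    stop("percent_volume: volumes must be a numeric matrix")
  }
  if (any(volumes < 0)) stop("percent_volume: negative spot volume")
  totals <- colSums(volumes)
  if (any(totals == 0)) {
    stop("percent_volume: gel(s) with zero total volume: ",
         paste(colnames(volumes)[totals == 0], collapse = ", "))
  }
  sweep(volumes, 2L, totals / 100, `/`)
}

#' Per-spot expression ratio and significance across gels
#'
#' For each spot, the ratio of the mean t48 percent volume to the mean t0
#' percent volume across gels, and a two-sided classical Student t-test
#' across the gels of the two conditions.
#'
#' @param pct Percent-volume matrix (spots x gels), e.g. from
#'   [percent_volume()].
#' @param gels Data frame with columns `gel_id` and `condition`
#'   (`"t0"`/`"t48"`); >= 2 gels per condition.
#' @return A data frame with columns `spot_id`, `mean_t0`, `mean_t48`,
#'   `ratio` (`NA` when the t0 mean is 0), `p_value`.
#' @export
spot_ratios <- function(pct, gels) {
  t0 <- gels$gel_id[gels$condition == "t0"]
  t48 <- gels$gel_id[gels$condition == "t48"]
  if (length(t0) < 2L || length(t48) < 2L) {
    stop("spot_ratios: need >= 2 gels per condition")
  }
  missing <- setdiff(c(t0, t48), colnames(pct))
  if (length(missing) > 0L) {
    stop("gel(s) absent from the spot table: ", paste(missing, collapse = ", "))
  }
  a <- pct[, t48, drop = FALSE]
  b <- pct[, t0, drop = FALSE]
  m_a <- rowMeans(a)
  m_b <- rowMeans(b)
  p <- vapply(seq_len(nrow(pct)), function(i) {
    xa <- a[i, ]
    xb <- b[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      return(if (m_a[i] == m_b[i]) 1 else 0)
    }
    stats::t.test(xa, xb, var.equal = TRUE)$p.value
  }, numeric(1L))
  data.frame(spot_id = rownames(pct), mean_t0 = unname(m_b),
             mean_t48 = unname(m_a),
             ratio = ifelse(m_b == 0, NA_real_, m_a / m_b),
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Significance-and-magnitude filter for protein changes
#'
#' A spot passes as up-regulated when `p < alpha` and its t48/t0 ratio shows
#' more than a `min_change` increase (`ratio >= 1 + min_change`), and as
#' down-regulated when `p < alpha` and the ratio shows the symmetric
#' decrease on the ratio scale (`ratio <= 1 / (1 + min_change)`; with
#' `symmetric = FALSE`, `ratio <= 1 - min_change`).
#'
#' @param ratios Data frame from [spot_ratios()] (columns `spot_id`,
#'   `ratio`, `p_value`).
#' @param alpha Significance threshold on the per-spot t-test.
#' @param min_change Minimal relative change (default 0.20 for 20%).
#' @param symmetric Symmetric cutoffs on the ratio scale (default) or the
#'   additive down cutoff `1 - min_change`.
#' @return A data frame with columns `spot_id`, `ratio`, `p_value`,
#'   `direction` (`up`/`down`/`unchanged`), `passes_filter`; spots with an
#'   undefined ratio are `unchanged`/`FALSE`.
#' @export
filter_protein_changes <- function(ratios, alpha = 0.05, min_change = 0.20,
                                   symmetric = TRUE) {
  up_cut <- 1 + min_change
  down_cut <- if (symmetric) 1 / (1 + min_change) else 1 - min_change
  r <- ratios$ratio
  p <- ratios$p_value
  ok <- !is.na(r) & !is.na(p)
  up <- ok & p < alpha & r >= up_cut
  down <- ok & p < alpha & r <= down_cut
  data.frame(spot_id = ratios$spot_id, ratio = r, p_value = p,
             direction = ifelse(up, "up", ifelse(down, "down", "unchanged")),
             passes_filter = up | down,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pair protein and mRNA ratios and call the trend
#'
#' Matches gene-identified protein ratios with the corresponding mRNA
#' ratios and calls each pair concordant when both ratios lie on the same
#' side of 1, discordant when on opposite sides, and boundary (excluded
#' from both counts) when either ratio equals 1 exactly. Unmatched genes
#' are skipped with a warning.
#'
#' @param protein_ratios Data frame with columns `gene`, `protein_ratio`.
#' @param mrna_ratios Data frame with columns `gene`, `mrna_ratio`.
#' @return A list with `pairs` (data frame: gene, protein_ratio,
#'   mrna_ratio, trend), `n_concordant`, `n_discordant`, `n_boundary`.
#' @export
pair_trends <- function(protein_ratios, mrna_ratios) {
  unmatched <- setdiff(protein_ratios$gene, mrna_ratios$gene)
  if (length(unmatched) > 0L) {
    warning("skipping gene(s) without an mRNA ratio: ",
            paste(unmatched, collapse = ", "))
  }
  common <- intersect(protein_ratios$gene, mrna_ratios$gene)
  pr <- protein_ratios$protein_ratio[match(common, protein_ratios$gene)]
  mr <- mrna_ratios$mrna_ratio[match(common, mrna_ratios$gene)]
  side <- function(v) sign(v - 1)
  trend <- ifelse(side(pr) == 0 | side(mr) == 0, "boundary",
                  ifelse(side(pr) == side(mr), "concordant", "discordant"))
  pairs <- data.frame(gene = common, protein_ratio = pr, mrna_ratio = mr,
                      trend = trend, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       n_concordant = sum(trend == "concordant"),
       n_discordant = sum(trend == "discordant"),
       n_boundary = sum(trend == "boundary"))
}
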