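#' Extract the significant signature of a differential-expression table
#'
#' @param de_table A [run_de()] result.
#' @param id_prefix Optional prefix prepended to probeset ids (to emulate a
#'   different array platform's identifiers).
#' @return Data frame with columns `id`, `log_ratio`, restricted to
#'   significant probesets.
#' @export
de_signature <- function(de_table, id_prefix = "") {
  sig <- de_table[de_table$significant, , drop = FALSE]
  data.frame(id = paste0(id_prefix, sig$probeset),
             log_ratio = sig$log2_fold_change,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Merge single-gene signatures with a trisomic signature
#'
#' Builds the paired log-ratio set used for sign-concordance analysis. The
#' trisomic table is first translated onto the overexpression platform
#' through the id map (many-to-one; when several source probesets map to
#' one target, the x of largest absolute value is kept). Per experiment,
#' the pair list is the intersection of the (already significance-filtered)
#' gene lists. The pooled list merges the per-experiment lists and removes
#' duplicate genes by keeping, for each gene, the pair whose y has the
#' largest absolute value, discarding the others.
#'
#' @param oe_signatures Named list (one element per overexpression
#'   experiment) of data frames with columns `id`, `log_ratio`, already
#'   restricted to significant genes.
#' @param trisomic_table Data frame with columns `id`, `log_ratio`
#'   (significant trisomic genes, source-platform ids when `idmap` given).
#' @param idmap Optional data frame (`source_id`, `target_id`) mapping the
#'   trisomic platform onto the overexpression platform.
#' @return A list of class `concordance_set` with `pairs` (data frame:
#'   gene, x, y, experiment; pooled, deduplicated), `per_experiment` (list
#'   of per-experiment pair data frames), `n`, `k`.
#' @export
map_and_merge <- function(oe_signatures, trisomic_table, idmap = NULL) {
  stopifnot(is.list(oe_signatures), !is.null(names(oe_signatures)))
  tri <- data.frame(id = trisomic_table$id,
                    x = trisomic_table$log_ratio, stringsAsFactors = FALSE)
  if (!is.null(idmap)) {
    m <- match(tri$id, idmap$source_id)
    tri <- tri[!is.na(m), , drop = FALSE]
    tri$id <- idmap$target_id[m[!is.na(m)]]
  }
  if (nrow(tri) > 0L && anyDuplicated(tri$id)) {
    tri <- tri[order(-abs(tri$x)), , drop = FALSE]
    tri <- tri[!duplicated(tri$id), , drop = FALSE]
  }

  per_exp <- lapply(names(oe_signatures), function(ex) {
    sig <- oe_signatures[[ex]]
    common <- intersect(sig$id, tri$id)
    if (length(common) == 0L) {
      return(data.frame(gene = character(), x = numeric(), y = numeric(),
                        experiment = character(), stringsAsFactors = FALSE))
    }
    data.frame(gene = common,
               x = tri$x[match(common, tri$id)],
               y = sig$log_ratio[match(common, sig$id)],
               experiment = ex, stringsAsFactors = FALSE)
  })
  names(per_exp) <- names(oe_signatures)

  pooled <- do.call(rbind, per_exp)
  rownames(pooled) <- NULL
  if (nrow(pooled) == 0L) {
    warning("no genes significant in both the trisomic and any overexpression signature")
  } else {
    pooled <- pooled[order(-abs(pooled$y)), , drop = FALSE]
    pooled <- pooled[!duplicated(pooled$gene), , drop = FALSE]
    rownames(pooled) <- NULL
  }
  kn <- same_sign_count(pooled$x, pooled$y)
  structure(list(pairs = pooled, per_experiment = per_exp,
                 n = kn[["n"]], k = kn[["k"]]),
            class = "concordance_set")
}

#' Count same-sign pairs
#'
#' A pair is same-sign when `x * y > 0` strictly; pairs with a zero
#' coordinate count toward `n` but never toward `k`.
#'
#' @param x,y Finite numeric vectors of equal length.
#' @return Named vector `c(k = same-sign count, n = pair count)`.
#' @export
same_sign_count <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("same_sign_count: non-finite coordinates")
  }
  c(k = sum(x * y > 0), n = length(x))
}

#' Resampling p-value for the observed same-sign concordance
#'
#' Creates `n_sets` sets of `n` (x, y) pairs by randomly extracting x from
#' `x_list` and y from `y_list` (independently, with replacement by
#' default; `replace = FALSE` draws each set without replacement from both
#' lists and pairs them in draw order). The p-value is the fraction of sets
#' in which at least `k` of the `n` pairs satisfy `x * y > 0`. When no set
#' qualifies the p-value 0 is reported together with the resolution bound
#' `1 / n_sets`.
#'
#' @param x_list,y_list Non-empty numeric vectors of log ratios.
#' @param n Pairs per set.
#' @param k Observed same-sign count (0 <= k <= n).
#' @param n_sets Number of resampled sets (>= 1000; default 100,000, with
#'   1,000,000 used for the most extreme comparisons).
#' @param seed Integer seed.
#' @param replace Draw with replacement (default) or without.
#' @return A list with `p_value`, `n_qualifying`, `n_sets`, `bound`
#'   (`1/n_sets`, the smallest resolvable non-zero p) and `at_resolution`
#'   (`TRUE` when no set qualified, i.e. p < bound).
#' @export
permutation_pvalue <- function(x_list, y_list, n, k, n_sets = 1e5,
                               seed = 1L, replace = TRUE) {
  if (length(x_list) == 0L || length(y_list) == 0L) {
    stop("permutation_pvalue: empty log-ratio list")
  }
  if (k > n) stop("permutation_pvalue: k cannot exceed n")
  if (k < 0) stop("permutation_pvalue: k must be >= 0")
  if (n_sets < 1000) stop("permutation_pvalue: n_sets must be >= 1000")
  if (!replace && (n > length(x_list) || n > length(y_list))) {
    stop("without replacement, n cannot exceed the list lengths")
  }
  n_sets <- as.integer(round(n_sets))
  sx <- sign(x_list)
  sy <- sign(y_list)
  n_qual <- withr::with_seed(as.integer(seed), {
    if (replace) {
      total <- 0L
      chunk <- max(1L, min(n_sets, as.integer(5e6) %/% n))
      done <- 0L
      while (done < n_sets) {
        m <- min(chunk, n_sets - done)
        ix <- sample.int(length(sx), n * m, replace = TRUE)
        iy <- sample.int(length(sy), n * m, replace = TRUE)
        same <- (sx[ix] * sy[iy]) > 0
        counts <- colSums(matrix(same, nrow = n, ncol = m))
        total <- total + sum(counts >= k)
        done <- done + m
      }
      total
    } else {
      qual <- vapply(seq_len(n_sets), function(i) {
        xs <- sx[sample.int(length(sx), n)]
        ys <- sy[sample.int(length(sy), n)]
        sum(xs * ys > 0) >= k
      }, logical(1L))
      sum(qual)
    }
  })
  p <- n_qual / n_sets
  list(p_value = p, n_qualifying = n_qual, n_sets = n_sets,
       bound = 1 / n_sets, at_resolution = n_qual == 0L)
}

#' Closed-form null for the same-sign concordance count
#'
#' Independent oracle for [permutation_pvalue()]. With-replacement variant:
#' each resampled pair is same-sign with probability
#' `q = fx fy + (1 - fx)(1 - fy)` independently, so the same-sign count is
#' Binomial(n, q) and the p-value is its upper tail at k.
#' Without-replacement pairing variant: with `a = round(fx n)` positive x
#' and `b = round(fy n)` positive y paired by a random permutation, the
#' number of positive-positive matches X is hypergeometric and the
#' same-sign count equals `n - a - b + 2X`; the p-value sums the
#' hypergeometric tail over X with `n - a - b + 2X >= k`. Zeros are assumed
#' absent from the lists.
#'
#' @param frac_pos_x,frac_pos_y Fractions of positive entries, in `[0, 1]`.
#' @param n Pairs per set.
#' @param k Same-sign threshold.
#' @param variant `"binomial"` (with replacement) or `"hypergeometric"`
#'   (without-replacement pairing).
#' @return The closed-form p-value `P(same-sign count >= k)`.
#' @export
concordance_null_oracle <- function(frac_pos_x, frac_pos_y, n, k,
                                    variant = c("binomial", "hypergeometric")) {
  variant <- match.arg(variant)
  if (frac_pos_x < 0 || frac_pos_x > 1 || frac_pos_y < 0 || frac_pos_y > 1) {
    stop("sign fractions must lie in [0, 1]")
  }
  if (k > n || k < 0) stop("need 0 <= k <= n")
  if (variant == "binomial") {
    q <- frac_pos_x * frac_pos_y + (1 - frac_pos_x) * (1 - frac_pos_y)
    stats::pbinom(k - 1, n, q, lower.tail = FALSE)
  } else {
    a <- round(frac_pos_x * n)
    b <- round(frac_pos_y * n)
    xs <- max(0L, a + b - n):min(a, b)
    s <- n - a - b + 2 * xs
    sum(stats::dhyper(xs[s >= k], a, n - a, b))
  }
}

#' Origin-forced regression and non-centered correlation
#'
#' Fits `y = A x` through the origin: `A = sum(xy) / sum(x^2)` (the
#' least-squares minimizer without intercept), with the non-centered
#' correlation coefficient `r = sum(xy) / sqrt(sum(x^2) sum(y^2))` and a
#' p-value from the Student-t transformation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, >= 3 pairs, `sum(x^2) > 0`.
#' @return A list with `slope`, `r_noncentered`, `t_stat`, `p_value`, `n`.
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("origin_regression: need >= 3 pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("origin_regression: all x are zero")
  sxy <- sum(x * y)
  syy <- sum(y^2)
  slope <- sxy / sxx
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(slope = slope, r_noncentered = r, t_stat = t_stat, p_value = p, n = n)
}

#' Full concordance statistics for a merged pair set
#'
#' Pooled and per-experiment same-sign counts, resampling p-values and
#' origin-forced regression for a [map_and_merge()] result.
#'
#' @param cset A `concordance_set`.
#' @param n_sets Resampled sets for the p-values.
#' @param seed Integer seed.
#' @param replace Resampling variant passed to [permutation_pvalue()].
#' @return A data frame with one row per experiment plus a `pooled` row:
#'   columns `experiment`, `n`, `k`, `p_perm`, `slope`, `r_noncentered`,
#'   `p_regression`.
#' @export
concordance_stats <- function(cset, n_sets = 1e5, seed = 1L,
                              replace = TRUE) {
  stopifnot(inherits(cset, "concordance_set"))
  one <- function(pairs, label, seed_off) {
    kn <- same_sign_count(pairs$x, pairs$y)
    if (kn[["n"]] >= 3L && sum(pairs$x^2) > 0) {
      reg <- origin_regression(pairs$x, pairs$y)
      pp <- permutation_pvalue(pairs$x, pairs$y, n = kn[["n"]],
                               k = kn[["k"]], n_sets = n_sets,
                               seed = derive_seed(seed, seed_off),
                               replace = replace)
      data.frame(experiment = label, n = kn[["n"]], k = kn[["k"]],
                 p_perm = pp$p_value, slope = reg$slope,
                 r_noncentered = reg$r_noncentered,
                 p_regression = reg$p_value, stringsAsFactors = FALSE)
    } else {
      data.frame(experiment = label, n = kn[["n"]], k = kn[["k"]],
                 p_perm = NA_real_, slope = NA_real_,
                 r_noncentered = NA_real_, p_regression = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(seq_along(cset$per_experiment), function(i) {
    one(cset$per_experiment[[i]], names(cset$per_experiment)[i], i)
  })
  rows[[length(rows) + 1L]] <- one(cset$pairs, "pooled", 0L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
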