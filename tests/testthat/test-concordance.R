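test_that("same-sign counting is strict about zeros", {
  expect_equal(same_sign_count(c(1, -1, 1), c(2, -3, -1)),
               c(k = 2, n = 3))
  expect_equal(same_sign_count(c(0, 1), c(5, 5))[["k"]], 1)
  expect_equal(same_sign_count(numeric(0), numeric(0)),
               c(k = 0, n = 0))
  expect_error(same_sign_count(1, c(1, 2)), "equal length")
  expect_error(same_sign_count(NA_real_, 1), "finite")
})

test_that("the same-sign fraction of symmetric random pairs approaches 1/2", {
  withr::with_seed(51L, {
    x <- rnorm(1e5)
    y <- rnorm(1e5)
    kn <- same_sign_count(x, y)
    expect_lt(abs(kn[["k"]] / kn[["n"]] - 0.5), 3 * sqrt(0.25 / 1e5))
  })
})

test_that("merging keeps the largest-|y| pair per gene and maps platforms", {
  sigs <- list(exp1 = data.frame(id = c("gA", "gB"), log_ratio = c(0.5, 1.0)),
               exp2 = data.frame(id = c("gA", "gC"), log_ratio = c(-0.8, 2.0)))
  tri <- data.frame(id = c("gA", "gB", "gC", "gD"),
                    log_ratio = c(0.3, -0.2, 0.9, 1.1))
  cset <- map_and_merge(sigs, tri)
  expect_equal(cset$n, 3)
  expect_equal(cset$pairs$y[cset$pairs$gene == "gA"], -0.8)
  expect_identical(sort(cset$pairs$gene), c("gA", "gB", "gC"))

  # id mapping with a many-to-one source keeps the largest |x|
  tri_alt <- data.frame(id = c("alt_gA", "alt_gA_b", "alt_gB"),
                        log_ratio = c(0.3, -0.9, 0.4))
  idmap <- data.frame(source_id = c("alt_gA", "alt_gA_b", "alt_gB"),
                      target_id = c("gA", "gA", "gB"))
  cset2 <- map_and_merge(sigs["exp1"], tri_alt, idmap)
  expect_equal(cset2$pairs$x[cset2$pairs$gene == "gA"], -0.9)

  # disjoint significant sets give an empty pair set with a warning
  expect_warning(
    empty <- map_and_merge(list(e = data.frame(id = "gZ", log_ratio = 1)),
                           tri),
    "no genes")
  expect_equal(empty$n, 0)
})

test_that("resampling p-values hit their degenerate limits", {
  x <- c(-1.2, 0.5, 2, -0.3)
  y <- c(1, 1, -2, 0.4)
  expect_equal(permutation_pvalue(x, y, n = 4, k = 0, n_sets = 1000)$p_value, 1)
  pos <- c(0.5, 1, 2)
  expect_equal(permutation_pvalue(pos, pos, n = 3, k = 3,
                                  n_sets = 1000)$p_value, 1)
  expect_error(permutation_pvalue(x, y, n = 3, k = 4, n_sets = 1000),
               "exceed")
  expect_error(permutation_pvalue(x, y, n = 3, k = 2, n_sets = 10), "1000")
  expect_error(permutation_pvalue(x, y, n = 10, k = 2, n_sets = 1000,
                                  replace = FALSE), "without replacement")
  a <- permutation_pvalue(x, y, 4, 3, n_sets = 2000, seed = 9L)
  b <- permutation_pvalue(x, y, 4, 3, n_sets = 2000, seed = 9L)
  expect_identical(a$p_value, b$p_value)
})

test_that("p_perm is monotone non-increasing in k", {
  withr::with_seed(53L, {
    x <- rnorm(60)
    y <- rnorm(60)
  })
  ps <- vapply(c(20, 30, 40, 50), function(k) {
    permutation_pvalue(x, y, n = 60, k = k, n_sets = 5000, seed = 4L)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("positive rescaling changes neither the concordance nor the correlation", {
  withr::with_seed(57L, {
    x <- rnorm(50)
    y <- 0.8 * x + rnorm(50, sd = 0.5)
  })
  kn <- same_sign_count(x, y)
  reg <- origin_regression(x, y)
  for (cx in c(0.01, 3)) {
    kn2 <- same_sign_count(cx * x, 7 * y)
    reg2 <- origin_regression(cx * x, 7 * y)
    expect_equal(kn2, kn)
    expect_equal(reg2$r_noncentered, reg$r_noncentered, tolerance = 1e-12)
  }
})

test_that("closed-form null matches exhaustive enumeration for small n", {
  expect_equal(concordance_null_oracle(0.5, 0.5, 2, 2), 0.25)
  expect_equal(concordance_null_oracle(1, 1, 5, 3), 1)
  expect_equal(concordance_null_oracle(1, 1, 5, 5), 1)
  expect_error(concordance_null_oracle(1.5, 0.5, 5, 2), "\\[0, 1\\]")
  for (n in c(4, 6, 8)) {
    for (f in c(0.25, 0.5, 0.75)) {
      for (k in 0:n) {
        expect_equal(concordance_null_oracle(f, f, n, k),
                     same_sign_tail_enumeration(f, f, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the hypergeometric variant matches brute-force permutation enumeration", {
  # n = 6, 4 positive x, 3 positive y: enumerate all 6! pairings
  n <- 6
  xs <- c(1, 1, 1, 1, -1, -1)
  ys <- c(1, 1, 1, -1, -1, -1)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  counts <- vapply(perms(ys), function(py) sum(xs * py > 0), numeric(1))
  for (k in 0:n) {
    expect_equal(concordance_null_oracle(4 / 6, 3 / 6, n, k,
                                         variant = "hypergeometric"),
                 mean(counts >= k), tolerance = 1e-12)
  }
})

test_that("origin-forced regression matches its closed form and a numeric minimizer", {
  reg <- origin_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(reg$slope, 2)
  expect_equal(reg$r_noncentered, 1)
  expect_equal(reg$p_value, 0)

  reg0 <- origin_regression(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(reg0$slope, 0)
  expect_equal(reg0$r_noncentered, 0)

  withr::with_seed(61L, {
    x <- rnorm(40)
    y <- 1.7 * x + rnorm(40)
  })
  reg <- origin_regression(x, y)
  sse <- function(a) sum((y - a * x)^2)
  opt <- stats::optimize(sse, c(-100, 100), tol = 1e-12)
  expect_equal(reg$slope, opt$minimum, tolerance = 1e-6)
  expect_error(origin_regression(c(0, 0, 0), c(1, 2, 3)), "all x are zero")
  expect_error(origin_regression(1:2, 1:2), ">= 3")
})

test_that("an additive trisomic signature yields strong sign concordance", {
  cfg <- sim_config(n_probesets = 600L, n_targets = 40L, seed = 71L,
                    truth_seed = 71L)
  res <- run_concordance_study(cfg, additive = TRUE, use_idmap = TRUE)
  expect_gt(res$cset$n, 0)
  expect_gt(res$cset$k / res$cset$n, 0.5)
  stats_tab <- concordance_stats(res$cset, n_sets = 2000, seed = 5L)
  pooled <- stats_tab[stats_tab$experiment == "pooled", ]
  expect_lt(pooled$p_perm, 0.01)
  expect_gt(pooled$r_noncentered, 0.5)
})

test_that("a non-additive trisomic signature shows null-level concordance", {
  fracs <- c()
  ns <- c()
  for (s in 1:25) {
    cfg <- sim_config(n_probesets = 400L, n_targets = 30L, n_genes = 10L,
                      noise_sd = 0.25, seed = 700L + s, truth_seed = 700L + s)
    res <- run_concordance_study(cfg, additive = FALSE)
    if (res$cset$n > 0) {
      fracs <- c(fracs, res$cset$k)
      ns <- c(ns, res$cset$n)
    }
  }
  total_k <- sum(fracs)
  total_n <- sum(ns)
  expect_gt(total_n, 30)
  # pooled same-sign fraction within 3 binomial sd of 1/2
  expect_lt(abs(total_k / total_n - 0.5), 3 * sqrt(0.25 / total_n))
})
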