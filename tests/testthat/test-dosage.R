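test_that("basal ranking sorts by mean with lexicographic tie-breaks", {
  m <- matrix(c(8, 8, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("pB", "pA"), c("s1", "s2")))
  rk <- basal_ranking(m)
  expect_identical(rk$id, c("pB", "pA"))
  expect_equal(rk$metric, c(8, 5))

  m_const <- matrix(3, 4, 2,
                    dimnames = list(c("pC", "pA", "pD", "pB"), c("s1", "s2")))
  expect_identical(basal_ranking(m_const)$id, c("pA", "pB", "pC", "pD"))
  expect_error(basal_ranking(m[0, , drop = FALSE]), "probeset rownames|empty")
})

test_that("silent transgene reporters rank above effective ones in basal expression", {
  cfg <- sim_config(seed = 31L, truth_seed = 31L)
  oe <- simulate_overexpression_study(cfg)
  rk <- basal_ranking(oe$expr)
  pos <- match(oe$truth$genes$transgene_probeset, rk$id)
  sil <- pos[oe$truth$genes$label == "silent"]
  eff <- pos[oe$truth$genes$label == "effective"]
  expect_lt(stats::median(sil), stats::median(eff))
})

test_that("enrichment score matches hand-computed extremes", {
  profile <- data.frame(id = letters[1:5], metric = c(5, 4, 3, 2, 1),
                        stringsAsFactors = FALSE)
  expect_equal(gsea_enrichment_score(profile, "a"), 1.0)
  expect_equal(gsea_enrichment_score(profile, "e"), -1.0)
  expect_error(gsea_enrichment_score(profile, "zz"), "intersect")
  expect_error(gsea_enrichment_score(profile, letters[1:5]), "entire")
})

test_that("enrichment score equals the exhaustive running-sum oracle for N <= 8", {
  set.seed(17)
  for (n in c(3, 5, 8)) {
    profile <- data.frame(id = sprintf("g%d", seq_len(n)),
                          metric = sort(runif(n, 0.1, 5), decreasing = TRUE),
                          stringsAsFactors = FALSE)
    for (mask in seq_len(2^n - 2)) {
      members <- profile$id[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (length(members) == 0 || length(members) == n) next
      for (p_w in c(0, 1, 2)) {
        expect_equal(gsea_enrichment_score(profile, members, p_w),
                     gsea_oracle(profile$metric, profile$id %in% members, p_w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("weight 0 gives the Kolmogorov-Smirnov statistic between hit and miss positions", {
  set.seed(23)
  n <- 40
  profile <- data.frame(id = sprintf("g%02d", 1:n),
                        metric = sort(rnorm(n, 8), decreasing = TRUE),
                        stringsAsFactors = FALSE)
  members <- sample(profile$id, 12)
  es <- gsea_enrichment_score(profile, members, weight_p = 0)
  hit_pos <- which(profile$id %in% members)
  miss_pos <- which(!profile$id %in% members)
  dif <- vapply(seq_len(n), function(i) {
    mean(hit_pos <= i) - mean(miss_pos <= i)
  }, numeric(1))
  expect_equal(abs(es), max(abs(dif)), tolerance = 1e-12)
})

test_that("the enrichment score depends only on the ranking order at weight 0", {
  set.seed(29)
  n <- 30
  profile <- data.frame(id = sprintf("g%02d", 1:n),
                        metric = sort(rexp(n) + 1, decreasing = TRUE),
                        stringsAsFactors = FALSE)
  members <- sample(profile$id, 8)
  transformed <- profile
  transformed$metric <- log(profile$metric) * 3 + 2  # strictly monotone
  expect_equal(gsea_enrichment_score(profile, members, 0),
               gsea_enrichment_score(transformed, members, 0))
})

test_that("set-permutation p-values respect the add-one lower bound and null uniformity", {
  set.seed(37)
  n <- 200
  profile <- data.frame(id = sprintf("g%03d", 1:n),
                        metric = sort(rnorm(n, 8, 2), decreasing = TRUE),
                        stringsAsFactors = FALSE)
  res <- gsea_significance(profile, sample(profile$id, 15), n_perm = 100L,
                           seed = 1L)
  expect_gte(res$p_value, 1 / 101)
  expect_error(gsea_significance(profile, profile$id[1], n_perm = 10L), "100")

  # random sets give approximately uniform p-values across seeds
  ps <- vapply(1:150, function(s) {
    members <- withr::with_seed(1000L + s, sample(profile$id, 15))
    gsea_significance(profile, members, n_perm = 200L,
                      seed = 2000L + s)$p_value
  }, numeric(1))
  # add-one p-values of random sets are approximately uniform: their
  # empirical CDF at a few interior points stays within 3 binomial sd
  for (q in c(0.2, 0.5, 0.8)) {
    expect_lt(abs(mean(ps <= q) - q), 3 * sqrt(q * (1 - q) / 150) + 1 / 201)
  }
})

test_that("disorder scores are residue-union cardinalities", {
  expect_identical(disorder_score(data.frame(start = integer(),
                                             end = integer())), 0L)
  expect_identical(disorder_score(data.frame(start = 1, end = 180)), 180L)
  expect_identical(disorder_score(data.frame(start = c(10, 30),
                                             end = c(40, 60))), 51L)
  expect_error(disorder_score(data.frame(start = 50, end = 40)), "start > end")
  set.seed(41)
  for (i in 1:30) {
    k <- sample(1:8, 1)
    start <- sample(1:300, k)
    intervals <- data.frame(start = start,
                            end = start + sample(0:80, k, replace = TRUE))
    expect_identical(disorder_score(intervals),
                     residue_union_oracle(intervals))
  }
})

test_that("dosage classification flags label mismatches as exceptions", {
  scores <- c(A = 300, B = 250, C = 26, D = 40, E = 90)
  labels <- c(A = "effective", B = "effective", C = "effective",
              D = "silent", E = "silent")
  res <- classify_dosage(scores, labels, threshold = 180)
  expect_identical(attr(res, "exceptions"), "C")
  expect_identical(res$predicted[res$gene == "C"], "silent")

  # perfectly separated scores give no exceptions
  res2 <- classify_dosage(c(A = 200, B = 300, D = 10, E = 179),
                          c(A = "effective", B = "effective",
                            D = "silent", E = "silent"))
  expect_length(attr(res2, "exceptions"), 0L)

  # excluded genes are dropped before classification
  res3 <- classify_dosage(scores, labels, exclude = "C")
  expect_false("C" %in% res3$gene)
  expect_error(classify_dosage(scores, labels, threshold = -1), "> 0")
})

test_that("raising the threshold never flips a prediction from silent to effective", {
  set.seed(43)
  scores <- stats::setNames(sample(0:500, 40), sprintf("g%02d", 1:40))
  labels <- stats::setNames(sample(c("effective", "silent"), 40, TRUE),
                            names(scores))
  prev <- classify_dosage(scores, labels, threshold = 1)$predicted
  for (theta in c(50, 180, 400, 600)) {
    cur <- classify_dosage(scores, labels, threshold = theta)$predicted
    expect_true(all(!(prev == "silent" & cur == "effective")))
    prev <- cur
  }
})

test_that("the disorder group test is antisymmetric in the labels", {
  scores <- c(a = 300, b = 260, c = 220, d = 40, e = 80, f = 120)
  labels <- c(a = "effective", b = "effective", c = "effective",
              d = "silent", e = "silent", f = "silent")
  res <- disorder_group_test(scores, labels)
  flipped <- ifelse(labels == "effective", "silent", "effective")
  res_f <- disorder_group_test(scores, stats::setNames(flipped, names(labels)))
  expect_equal(res$t_stat, -res_f$t_stat)
  expect_equal(res$p_value, res_f$p_value)
  expect_gt(res$t_stat, 0)

  same <- disorder_group_test(c(a = 1, b = 2, c = 1, d = 2),
                              c(a = "effective", b = "effective",
                                c = "silent", d = "silent"))
  expect_equal(same$p_value, 1)
  expect_error(disorder_group_test(c(a = 1, b = 2), c(a = "effective",
                                                      b = "silent")),
               ">= 2")
})

test_that("label separation is detected at study-like group sizes", {
  detected <- vapply(1:60, function(s) {
    withr::with_seed(5000L + s, {
      eff <- rnorm(7, 300, 80)
      sil <- rnorm(13, 80, 40)
      scores <- stats::setNames(c(eff, sil), sprintf("g%02d", 1:20))
      labels <- stats::setNames(rep(c("effective", "silent"), c(7, 13)),
                                names(scores))
      disorder_group_test(scores, labels)$p_value < 0.05
    })
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})
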