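#' Configuration for the synthetic dosage-imbalance study
#'
#' Collects every tunable parameter of the synthetic-data generators with
#' defaults matching the structure of the emulated study: 20 overexpressed
#' genes, 3 clones per gene, induced vs uninduced conditions (120 arrays),
#' a trisomic-vs-control comparison, and a 12-gel 2DGE experiment with a
#' small fraction of truly changed spots.
#'
#' Ground-truth structure (which genes are effective, planted effect sizes,
#' basal means) is drawn under `truth_seed`; measurement noise is drawn
#' under `seed`. Varying `seed` alone therefore changes the noise but not
#' the planted truth.
#'
#' @param n_genes Number of overexpressed genes.
#' @param n_clones Clones (biological replicates) per gene.
#' @param n_probesets Probesets on the simulated array.
#' @param noise_sd Replicate-level Gaussian noise sd, log2 units.
#' @param effect_size_mean,effect_size_sd Mean and sd of the absolute planted
#'   log2 effect on downstream targets of effective genes; signs are random.
#' @param n_targets Downstream target probesets perturbed per effective gene.
#' @param fraction_effective Fraction of genes planted as effective;
#'   `round(fraction_effective * n_genes)` genes are effective.
#' @param basal_quantile_for_silent Silent genes' transgene probesets get
#'   basal means drawn from this top quantile of the basal distribution
#'   (silent genes are highly endogenously expressed).
#' @param overexpression_log2 Log2 shift of a gene's own transgene probeset
#'   in induced samples (massive, not 3:2, induction).
#' @param n_parental Parental (non-transgenic) baseline samples.
#' @param n_leaky Number of genes planted with uninduced transgene leakage.
#' @param leak_log2 Log2 shift of the leaky genes' transgene probesets in
#'   uninduced clone samples.
#' @param between_clone_sd Sd of a per-(gene, clone) scalar array effect
#'   shared by both conditions of the clone; 0 disables it.
#' @param trisomic_group_size Samples per group in the trisomic comparison.
#' @param trisomic_scale Scale applied to the summed single-gene effects to
#'   form the additive trisomic shift; default `log2(3/2)` for a 3:2 dosage.
#' @param n_spots 2DGE spots.
#' @param fraction_spots_changed Fraction of spots with a planted change.
#' @param spot_noise_sdlog Lognormal sdlog of multiplicative gel noise.
#' @param seed Integer noise seed.
#' @param truth_seed Integer seed for the planted truth structure.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L,
                       n_clones = 3L,
                       n_probesets = 2000L,
                       noise_sd = 0.25,
                       effect_size_mean = 1.5,
                       effect_size_sd = 0.25,
                       n_targets = 100L,
                       fraction_effective = 0.35,
                       basal_quantile_for_silent = 0.2,
                       overexpression_log2 = 4,
                       n_parental = 3L,
                       n_leaky = 1L,
                       leak_log2 = 2,
                       between_clone_sd = 0,
                       trisomic_group_size = 4L,
                       trisomic_scale = log2(3 / 2),
                       n_spots = 500L,
                       fraction_spots_changed = 54 / 500,
                       spot_noise_sdlog = 0.08,
                       seed = 1L,
                       truth_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_clones = as.integer(n_clones),
              n_probesets = as.integer(n_probesets),
              noise_sd = noise_sd,
              effect_size_mean = effect_size_mean,
              effect_size_sd = effect_size_sd,
              n_targets = as.integer(n_targets),
              fraction_effective = fraction_effective,
              basal_quantile_for_silent = basal_quantile_for_silent,
              overexpression_log2 = overexpression_log2,
              n_parental = as.integer(n_parental),
              n_leaky = as.integer(n_leaky),
              leak_log2 = leak_log2,
              between_clone_sd = between_clone_sd,
              trisomic_group_size = as.integer(trisomic_group_size),
              trisomic_scale = trisomic_scale,
              n_spots = as.integer(n_spots),
              fraction_spots_changed = fraction_spots_changed,
              spot_noise_sdlog = spot_noise_sdlog,
              seed = as.integer(seed),
              truth_seed = as.integer(truth_seed))
  counts <- c("n_genes", "n_clones", "n_probesets", "n_targets",
              "trisomic_group_size", "n_spots")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop("sim_config: '", nm, "' must be a positive count")
    }
  }
  fracs <- c("fraction_effective", "basal_quantile_for_silent",
             "fraction_spots_changed")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("sim_config: '", nm, "' must lie in [0, 1]")
    }
  }
  if (cfg$noise_sd < 0 || cfg$effect_size_sd < 0 || cfg$between_clone_sd < 0 ||
      cfg$spot_noise_sdlog < 0) {
    stop("sim_config: standard deviations must be non-negative")
  }
  if (cfg$n_probesets < cfg$n_genes) {
    stop("sim_config: need at least one probeset per gene")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Derived sub-seeds keep the generators' streams distinct while remaining
# a deterministic function of the user-facing seeds (and < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset) %% 2147483629)
}

gene_ids <- function(n) sprintf("G%02d", seq_len(n))
probeset_ids <- function(n) sprintf("ps%04d", seq_len(n))

#' Plant the ground truth for an overexpression study
#'
#' Draws, under `config$truth_seed` only, the per-probeset basal means, the
#' effective/silent labels, each effective gene's downstream target effects,
#' the leaky genes, and the additive trisomic effect vector. The first
#' `n_genes` probesets act as the transgene reporter probesets, one per
#' gene. Silent genes' reporters get basal means from the top
#' `basal_quantile_for_silent` of the basal distribution; effective genes'
#' reporters from below its median.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `genes` (data frame:
#'   gene, label, transgene_probeset, leaky), `targets` (data frame: gene,
#'   probeset, effect), `basal_means` (named numeric), `trisomic_effects`
#'   (named numeric, the `trisomic_scale`-scaled sum of planted single-gene
#'   effects per probeset) and `config`.
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$truth_seed, 101L), {
    genes <- gene_ids(config$n_genes)
    probes <- probeset_ids(config$n_probesets)
    basal <- stats::rnorm(config$n_probesets, mean = 8, sd = 1.2)
    names(basal) <- probes
    transgene <- probes[seq_len(config$n_genes)]

    n_eff <- round(config$fraction_effective * config$n_genes)
    effective <- sort(sample(genes, n_eff))
    label <- ifelse(genes %in% effective, "effective", "silent")

    # silent reporters highly expressed, effective reporters lowly expressed
    q_hi <- stats::quantile(basal, 1 - config$basal_quantile_for_silent)
    q_lo <- stats::quantile(basal, 0.05)
    q_med <- stats::quantile(basal, 0.5)
    for (i in seq_along(genes)) {
      basal[transgene[i]] <- if (label[i] == "silent") {
        stats::runif(1, q_hi, max(basal) + 0.5)
      } else {
        stats::runif(1, q_lo, q_med)
      }
    }

    background <- setdiff(probes, transgene)
    target_list <- list()
    for (g in effective) {
      tg <- sample(background, min(config$n_targets, length(background)))
      magnitude <- abs(stats::rnorm(length(tg), config$effect_size_mean,
                                    config$effect_size_sd))
      sgn <- sample(c(-1, 1), length(tg), replace = TRUE)
      eff <- sgn * magnitude
      target_list[[g]] <- data.frame(gene = g, probeset = tg, effect = eff,
                                     stringsAsFactors = FALSE)
    }
    targets <- if (length(target_list) > 0L) {
      do.call(rbind, target_list)
    } else {
      data.frame(gene = character(), probeset = character(),
                 effect = numeric(), stringsAsFactors = FALSE)
    }
    rownames(targets) <- NULL
    targets <- targets[abs(targets$effect) > 0, , drop = FALSE]

    # a gene with no non-zero planted effect is silent by definition
    has_effect <- genes %in% targets$gene
    label[label == "effective" & !has_effect] <- "silent"

    leaky_genes <- character(0)
    if (config$n_leaky > 0L) {
      eff_now <- genes[label == "effective"]
      pool <- if (length(eff_now) >= config$n_leaky) eff_now else genes
      leaky_genes <- sort(sample(pool, min(config$n_leaky, length(pool))))
    }

    trisomic <- stats::setNames(numeric(config$n_probesets), probes)
    if (nrow(targets) > 0L) {
      sums <- tapply(targets$effect, targets$probeset, sum)
      trisomic[names(sums)] <- config$trisomic_scale * as.numeric(sums)
    }

    truth <- list(genes = data.frame(gene = genes, label = label,
                                     transgene_probeset = transgene,
                                     leaky = genes %in% leaky_genes,
                                     stringsAsFactors = FALSE),
                  targets = targets,
                  basal_means = basal,
                  trisomic_effects = trisomic,
                  config = config)
    class(truth) <- "sim_truth"
    truth
  })
}

#' Simulate an inducible overexpression study
#'
#' Generates a log2-scale expression matrix for `n_genes x n_clones x 2`
#' clone samples (induced and uninduced) plus `n_parental` parental baseline
#' samples. Induced samples carry the gene's own transgene shift
#' (`overexpression_log2`) and, for effective genes, the planted downstream
#' target effects; uninduced samples are baseline plus noise, except leaky
#' genes whose reporters are shifted by `leak_log2` in the uninduced state.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-planted [plant_truth()] result; planted from
#'   `config` when omitted.
#' @return A list with elements `expr` (matrix), `samples` (annotation data
#'   frame) and `truth` (`sim_truth`).
#' @export
simulate_overexpression_study <- function(config, truth = plant_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- truth$genes$gene
  probes <- names(truth$basal_means)

  grid <- expand.grid(condition = c("uninduced", "induced"),
                      clone = seq_len(config$n_clones),
                      gene = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "clone", "condition")]
  samples <- data.frame(
    sample_id = sprintf("%s_c%d_%s", grid$gene, grid$clone,
                        ifelse(grid$condition == "induced", "ind", "uni")),
    experiment_gene = grid$gene,
    clone_id = sprintf("%s_c%d", grid$gene, grid$clone),
    condition = grid$condition,
    timepoint_h = ifelse(grid$condition == "induced", 24, 0),
    stringsAsFactors = FALSE)
  if (config$n_parental > 0L) {
    parental <- data.frame(
      sample_id = sprintf("parental_%d", seq_len(config$n_parental)),
      experiment_gene = "parental",
      clone_id = "parental",
      condition = "parental",
      timepoint_h = 0,
      stringsAsFactors = FALSE)
    samples <- rbind(samples, parental)
  }

  expr <- withr::with_seed(derive_seed(config$seed, 211L), {
    m <- matrix(stats::rnorm(length(probes) * nrow(samples),
                             sd = config$noise_sd),
                nrow = length(probes),
                dimnames = list(probes, samples$sample_id))
    m <- m + truth$basal_means
    if (config$between_clone_sd > 0) {
      clones <- unique(samples$clone_id)
      shift <- stats::setNames(
        stats::rnorm(length(clones), sd = config$between_clone_sd), clones)
      m <- sweep(m, 2L, shift[samples$clone_id], `+`)
    }
    m
  })

  tg <- stats::setNames(truth$genes$transgene_probeset, truth$genes$gene)
  for (i in seq_len(nrow(samples))) {
    g <- samples$experiment_gene[i]
    if (g == "parental") next
    if (samples$condition[i] == "induced") {
      expr[tg[[g]], i] <- expr[tg[[g]], i] + config$overexpression_log2
      tgt <- truth$targets[truth$targets$gene == g, , drop = FALSE]
      if (nrow(tgt) > 0L) {
        expr[tgt$probeset, i] <- expr[tgt$probeset, i] + tgt$effect
      }
    } else if (truth$genes$leaky[truth$genes$gene == g]) {
      expr[tg[[g]], i] <- expr[tg[[g]], i] + config$leak_log2
    }
  }
  validate_expression_matrix(expr)
  list(expr = expr, samples = samples, truth = truth)
}

#' Simulate a trisomic-vs-control comparison
#'
#' Two groups of `trisomic_group_size` samples over the same probesets as
#' the overexpression study. With `additive = TRUE` the trisomic group is
#' shifted per probeset by `truth$trisomic_effects`, the scaled sum of the
#' planted single-gene effects; with `additive = FALSE` the same shift
#' magnitudes are permuted across probesets, producing a trisomic signature
#' unrelated to the single-gene truth.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` from [plant_truth()] /
#'   [simulate_overexpression_study()].
#' @param additive Logical; plant the additive single-gene combination or an
#'   unrelated signature of the same magnitude distribution.
#' @return A list with elements `expr` and `samples`.
#' @export
simulate_trisomic_study <- function(config, truth, additive = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "sim_truth")) {
    stop("simulate_trisomic_study requires the truth from plant_truth()")
  }
  probes <- names(truth$basal_means)
  n_per <- config$trisomic_group_size
  samples <- data.frame(
    sample_id = c(sprintf("tri_%d", seq_len(n_per)),
                  sprintf("ctl_%d", seq_len(n_per))),
    experiment_gene = "trisomic",
    clone_id = rep(c("trisomic", "control"), each = n_per),
    condition = rep(c("trisomic", "control"), each = n_per),
    timepoint_h = 0,
    stringsAsFactors = FALSE)

  withr::with_seed(derive_seed(config$seed, 307L), {
    shift <- truth$trisomic_effects
    if (!additive) shift <- stats::setNames(sample(shift), probes)
    expr <- matrix(stats::rnorm(length(probes) * nrow(samples),
                                sd = config$noise_sd),
                   nrow = length(probes),
                   dimnames = list(probes, samples$sample_id))
    expr <- expr + truth$basal_means
    tri_cols <- samples$condition == "trisomic"
    expr[, tri_cols] <- expr[, tri_cols] + shift
    validate_expression_matrix(expr)
    list(expr = expr, samples = samples)
  })
}

#' Simulate per-gene intrinsic disorder profiles
#'
#' Plants disordered-region intervals so that effective genes score at or
#' above the classification threshold (dosage-sensitive proteins are
#' disorder-rich) and silent genes score below it, with exactly one planted
#' exception: one effective gene with a low disorder score of 26 residues,
#' emulating the kinase outlier of the emulated study. Scores are the
#' summed lengths of non-overlapping intervals.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` carrying effective/silent labels.
#' @param threshold Planted separation threshold, residues.
#' @param exception_score Disorder score of the planted exception gene.
#' @return A list with `intervals` (data frame: gene, start, end) and
#'   `planted` (data frame: gene, label, score, exception).
#' @export
simulate_disorder_profiles <- function(config, truth, threshold = 180L,
                                       exception_score = 26L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  withr::with_seed(derive_seed(config$truth_seed, 401L), {
    genes <- truth$genes$gene
    label <- truth$genes$label
    score <- integer(length(genes))
    for (i in seq_along(genes)) {
      score[i] <- if (label[i] == "effective") {
        as.integer(max(threshold + 5L, round(stats::rnorm(1, 300, 80))))
      } else {
        as.integer(min(threshold - 5L, max(5L, round(stats::rnorm(1, 80, 40)))))
      }
    }
    exception <- rep(FALSE, length(genes))
    eff_idx <- which(label == "effective")
    if (length(eff_idx) > 0L) {
      pick <- sample(eff_idx, 1L)
      score[pick] <- as.integer(exception_score)
      exception[pick] <- TRUE
    }

    rows <- list()
    for (i in seq_along(genes)) {
      s <- score[i]
      if (s <= 0L) next
      k <- sample(1:3, 1L)
      k <- min(k, s)  # at least one residue per interval
      cuts <- sort(sample(seq_len(s - 1L), k - 1L))
      lens <- diff(c(0L, cuts, s))
      start <- 1L
      for (len in lens) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[i], start = start, end = start + len - 1L,
          stringsAsFactors = FALSE)
        start <- start + len + sample(5:30, 1L)  # gap between regions
      }
    }
    intervals <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(gene = character(), start = integer(), end = integer())
    rownames(intervals) <- NULL
    list(intervals = intervals,
         planted = data.frame(gene = genes, label = label, score = score,
                              exception = exception,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a 2DGE spot-volume table
#'
#' Twelve gels (2 clones x 3 technical replicates x t0/t48) of positive raw
#' spot volumes with multiplicative lognormal noise. A planted fraction of
#' spots changes between t0 and t48 with true ratios outside `[0.8, 1.2]`
#' (magnitudes between 1.3- and 3.3-fold, both directions); the remaining
#' spots have a true ratio of 1.
#'
#' @param config A [sim_config()]; requires `n_spots >= 10`.
#' @return A list with `volumes` (spots x gels raw-volume matrix), `gels`
#'   (data frame: gel_id, clone, condition, replicate) and `truth` (data
#'   frame: spot_id, direction, ratio).
#' @export
simulate_spot_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_spots < 10L) stop("simulate_spot_table needs n_spots >= 10")
  withr::with_seed(derive_seed(config$seed, 503L), {
    spots <- sprintf("spot%04d", seq_len(config$n_spots))
    gels <- expand.grid(replicate = 1:3,
                        condition = c("t0", "t48"),
                        clone = c("E6", "E7"),
                        stringsAsFactors = FALSE)
    gels <- gels[, c("clone", "condition", "replicate")]
    gels$gel_id <- sprintf("%s_%s_r%d", gels$clone, gels$condition,
                           gels$replicate)

    n_changed <- round(config$fraction_spots_changed * config$n_spots)
    changed <- sample(spots, n_changed)
    direction <- rep("unchanged", config$n_spots)
    ratio <- rep(1, config$n_spots)
    names(direction) <- names(ratio) <- spots
    if (n_changed > 0L) {
      up <- sample(c(TRUE, FALSE), n_changed, replace = TRUE)
      magnitude <- 2^stats::runif(n_changed, log2(1.3), log2(3.3))
      ratio[changed] <- ifelse(up, magnitude, 1 / magnitude)
      direction[changed] <- ifelse(up, "up", "down")
    }

    base <- stats::rlnorm(config$n_spots, meanlog = 10, sdlog = 1)
    volumes <- matrix(NA_real_, nrow = config$n_spots, ncol = nrow(gels),
                      dimnames = list(spots, gels$gel_id))
    for (j in seq_len(nrow(gels))) {
      mu <- if (gels$condition[j] == "t48") base * ratio else base
      volumes[, j] <- mu * stats::rlnorm(config$n_spots, 0,
                                         config$spot_noise_sdlog)
    }
    list(volumes = volumes,
         gels = gels[, c("gel_id", "clone", "condition", "replicate")],
         truth = data.frame(spot_id = spots, direction = unname(direction),
                            ratio = unname(ratio), stringsAsFactors = FALSE))
  })
}

#' Simulate an id-conversion table between two array platforms
#'
#' Produces a best-match style map from alternate-platform probeset ids to
#' the simulated platform's ids. A fraction of target probesets receive two
#' source probesets (many-to-one), mirroring real conversion tables.
#'
#' @param config A [sim_config()].
#' @param prefix Prefix of the alternate-platform ids.
#' @param fraction_duplicated Fraction of probesets with two source ids.
#' @return A data frame with columns `source_id`, `target_id`.
#' @export
simulate_id_map <- function(config, prefix = "alt_",
                            fraction_duplicated = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$truth_seed, 601L), {
    probes <- probeset_ids(config$n_probesets)
    map <- data.frame(source_id = paste0(prefix, probes),
                      target_id = probes, stringsAsFactors = FALSE)
    n_dup <- round(fraction_duplicated * config$n_probesets)
    if (n_dup > 0L) {
      dup <- sample(probes, n_dup)
      map <- rbind(map, data.frame(source_id = paste0(prefix, dup, "_b"),
                                   target_id = dup, stringsAsFactors = FALSE))
    }
    map[order(map$target_id), ]
  })
}
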