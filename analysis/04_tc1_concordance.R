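#!/usr/bin/env Rscript
# Stage 4: sign concordance of single-gene signatures with the trisomic one.
#
# Tests the trisomic-vs-control matrix with the same regularized-t + FDR
# pipeline, maps its probesets onto the overexpression platform, intersects
# significant genes per experiment, pools with largest-|y| deduplication,
# and assesses the same-sign fraction with the resampling null plus an
# origin-forced regression.

suppressPackageStartupMessages(library(dosage21))

tri_expr <- read_expression_matrix("scratch/simdata/trisomic_matrix.tsv")
tri_samples <- read_sample_annotation("scratch/simdata/trisomic_samples.tsv")
cls <- utils::read.delim("results/02_effective_classification.tsv",
                         stringsAsFactors = FALSE)
idmap <- read_id_map("scratch/simdata/idmap.tsv")

de_tri <- run_de(tri_expr, tri_samples, "trisomic",
                 conditions = c("trisomic", "control"))
stage_log("trisomic signature: ", sum(de_tri$significant),
          " significant probesets at FDR < 0.05")

effective <- cls$gene[cls$label == "effective"]
signatures <- lapply(effective, function(g) {
  de <- utils::read.delim(file.path("scratch/de", paste0(g, "_de.tsv")),
                          stringsAsFactors = FALSE)
  data.frame(id = de$probeset[de$significant],
             log_ratio = de$log2_fold_change[de$significant])
})
names(signatures) <- effective

# the trisomic platform uses alternate ids; map back through the conversion
tri_sig <- de_signature(de_tri, id_prefix = "alt_")
cset <- map_and_merge(signatures, tri_sig, idmap)

stats_tab <- concordance_stats(cset, n_sets = 1e5, seed = 29L)
utils::write.table(stats_tab, "results/04_concordance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cset$pairs, "results/04_concordance_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

pooled <- stats_tab[stats_tab$experiment == "pooled", ]
stage_log(sprintf(
  "pooled: %d of %d pairs same-sign (%.1f%%), resampling p = %.3g, slope = %.2f, r = %.2f",
  pooled$k, pooled$n, 100 * pooled$k / pooled$n, pooled$p_perm,
  pooled$slope, pooled$r_noncentered))
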