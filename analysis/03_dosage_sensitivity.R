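#!/usr/bin/env Rscript
# Stage 3: predict dosage sensitivity from basal expression and disorder.
#
# Ranks probesets by mean expression over all arrays, scores the enrichment
# of the silent-gene reporters near the top of that ranking (running-sum
# enrichment with a set-permutation null), then classifies genes by total
# disordered residues against the 180-residue threshold and compares group
# means with a t-test.

suppressPackageStartupMessages(library(dosage21))

expr <- read_expression_matrix("scratch/simdata/overexpression_matrix.tsv")
cls <- utils::read.delim("results/02_effective_classification.tsv",
                         stringsAsFactors = FALSE)
truth <- utils::read.delim("results/01_planted_truth.tsv",
                           stringsAsFactors = FALSE)
silent_set <- read_gene_sets("scratch/simdata/silent_set.gmt")$silent_reporters
intervals <- read_disorder_intervals("scratch/simdata/disorder_intervals.tsv")

ranking <- basal_ranking(expr)
enr <- gsea_significance(ranking, silent_set, n_perm = 2000L, seed = 17L)
stage_log(sprintf(
  "silent-set basal enrichment: ES = %.3f, p = %.4g, q = %.3g (2000 set permutations)",
  enr$es, enr$p_value, enr$q_value))

labels <- stats::setNames(cls$label, cls$gene)
scores <- disorder_scores(intervals, genes = cls$gene)
classified <- classify_dosage(scores, labels, threshold = 180)
gt <- disorder_group_test(scores, labels)

utils::write.table(classified, "results/03_disorder_classification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
reporter_rank <- match(truth$transgene_probeset, ranking$id)
utils::write.table(
  data.frame(gene = truth$gene, label = truth$label,
             basal_rank = reporter_rank,
             basal_mean = ranking$metric[reporter_rank],
             disorder_score = scores[truth$gene]),
  "results/03_basal_and_disorder.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

stage_log("disorder threshold 180: ",
          length(attr(classified, "exceptions")), " exception(s): ",
          paste(attr(classified, "exceptions"), collapse = ", "),
          " (planted exception: ",
          paste(truth$gene[truth$exception], collapse = ", "), ")")
stage_log(sprintf("effective-vs-silent disorder t-test: t = %.2f, p = %.4g",
                  gt$t_stat, gt$p_value))
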