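#!/usr/bin/env Rscript
# Stage 2: differential expression per overexpression experiment.
#
# For each gene, pools its clones and tests induced vs uninduced probesets
# with the regularized t + BH FDR, classifies genes as effective or silent,
# and tests uninduced transgene leakiness against the parental line.
# Requires stage 1 outputs under scratch/simdata/.

suppressPackageStartupMessages(library(dosage21))

expr <- read_expression_matrix("scratch/simdata/overexpression_matrix.tsv")
samples <- read_sample_annotation("scratch/simdata/overexpression_samples.tsv")
truth <- utils::read.delim("results/01_planted_truth.tsv",
                           stringsAsFactors = FALSE)
genes <- truth$gene
tg <- stats::setNames(truth$transgene_probeset, genes)

dir.create("scratch/de", showWarnings = FALSE, recursive = TRUE)
de_tables <- lapply(genes, function(g) {
  de <- run_de(expr, samples, g)
  utils::write.table(de, file.path("scratch/de", paste0(g, "_de.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  de
})
names(de_tables) <- genes

cls <- classify_effective(de_tables, transgene_map = tg)
leak <- leakiness_test(expr, samples, tg)

summary_tab <- merge(merge(cls, leak[, c("gene", "q_value", "leaky")],
                           by = "gene"),
                     truth[, c("gene", "label")], by = "gene",
                     suffixes = c("", "_planted"))
names(summary_tab)[names(summary_tab) == "q_value"] <- "leak_q"
utils::write.table(summary_tab, "results/02_effective_classification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

stage_log(sum(cls$label == "effective"), " of ", length(genes),
          " genes effective (planted: ",
          sum(truth$label == "effective"), "); agreement ",
          sum(cls$label == truth$label[match(cls$gene, truth$gene)]), "/",
          length(genes))
stage_log("leaky genes: ",
          paste(leak$gene[leak$leaky], collapse = ", "),
          " (planted: ", paste(truth$gene[truth$leaky], collapse = ", "), ")")
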