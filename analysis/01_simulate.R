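#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with recorded ground truth.
#
# Produces the inputs every later stage consumes: the overexpression
# expression matrix (20 genes x 3 clones x induced/uninduced, plus parental
# baselines), the trisomic-vs-control matrix, per-gene disorder intervals,
# the 2DGE spot-volume table, and a silent-gene set file. Large matrices go
# under scratch/ (regenerable); small summary tables under results/.

suppressPackageStartupMessages(library(dosage21))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

dir.create("scratch/simdata", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed, truth_seed = seed)
stage_log("simulating overexpression study: ", cfg$n_genes, " genes x ",
          cfg$n_clones, " clones x 2 conditions, ", cfg$n_probesets,
          " probesets, seed ", seed)

oe <- simulate_overexpression_study(cfg)
write_expression_matrix(oe$expr, "scratch/simdata/overexpression_matrix.tsv")
write_sample_annotation(oe$samples, "scratch/simdata/overexpression_samples.tsv")

tri <- simulate_trisomic_study(cfg, oe$truth, additive = TRUE)
write_expression_matrix(tri$expr, "scratch/simdata/trisomic_matrix.tsv")
write_sample_annotation(tri$samples, "scratch/simdata/trisomic_samples.tsv")

dp <- simulate_disorder_profiles(cfg, oe$truth)
utils::write.table(dp$intervals, "scratch/simdata/disorder_intervals.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

sp <- simulate_spot_table(cfg)
utils::write.table(data.frame(spot_id = rownames(sp$volumes), sp$volumes,
                              check.names = FALSE),
                   "scratch/simdata/spot_volumes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sp$gels, "scratch/simdata/gels.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

idmap <- simulate_id_map(cfg)
utils::write.table(idmap, "scratch/simdata/idmap.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)

silent <- oe$truth$genes$transgene_probeset[oe$truth$genes$label == "silent"]
write_gene_sets(list(silent_reporters = silent),
                "scratch/simdata/silent_set.gmt")

truth_tab <- merge(oe$truth$genes, dp$planted[, c("gene", "score", "exception")],
                   by = "gene")
utils::write.table(truth_tab, "results/01_planted_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sp$truth, "scratch/simdata/spot_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

stage_log("planted ", sum(oe$truth$genes$label == "effective"),
          " effective of ", cfg$n_genes, " genes; ",
          sum(sp$truth$direction != "unchanged"), " changed spots of ",
          cfg$n_spots, "; truth written to results/01_planted_truth.tsv")
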