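#!/usr/bin/env Rscript
# Stage 5: 2DGE differential proteome and protein-mRNA trend pairing.
#
# Normalizes spot volumes to percent volumes per gel, computes t48/t0
# ratios with per-spot Student t-tests across the 12 gels, applies the
# p < 0.05 AND >20% change filter, and pairs the published protein/mRNA
# ratio table to call concordant vs discordant trends.

suppressPackageStartupMessages(library(dosage21))

volumes_tab <- utils::read.delim("scratch/simdata/spot_volumes.tsv",
                                 check.names = FALSE)
volumes <- as.matrix(volumes_tab[, -1])
rownames(volumes) <- volumes_tab$spot_id
gels <- utils::read.delim("scratch/simdata/gels.tsv", stringsAsFactors = FALSE)
spot_truth <- utils::read.delim("scratch/simdata/spot_truth.tsv",
                                stringsAsFactors = FALSE)

pct <- percent_volume(volumes)
ratios <- spot_ratios(pct, gels)
changes <- filter_protein_changes(ratios)
utils::write.table(changes, "results/05_protein_changes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

called <- changes[changes$passes_filter, ]
planted <- spot_truth$spot_id[spot_truth$direction != "unchanged"]
stage_log(sum(changes$passes_filter), " spots pass p < 0.05 & >20% (",
          sum(called$direction == "up"), " up, ",
          sum(called$direction == "down"), " down); planted ",
          length(planted), "; overlap ",
          length(intersect(called$spot_id, planted)))

# published Runx1 protein/mRNA ratio pairs
tab <- utils::read.delim(
  system.file("extdata", "runx1_2dge_protein_mrna_ratios.tsv",
              package = "dosage21"), stringsAsFactors = FALSE)
trends <- pair_trends(tab[, c("gene", "protein_ratio")],
                      tab[, c("gene", "mrna_ratio")])
utils::write.table(trends$pairs, "results/05_protein_mrna_trends.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
stage_log("protein-mRNA trends: ", trends$n_concordant, " concordant, ",
          trends$n_discordant, " discordant, ", trends$n_boundary,
          " boundary of ", nrow(trends$pairs))
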