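# Shared pipeline drivers so tests exercise the same call sequence the
# analysis scripts use.

run_full_de_study <- function(cfg) {
  oe <- simulate_overexpression_study(cfg)
  genes <- oe$truth$genes$gene
  des <- lapply(genes, function(g) run_de(oe$expr, oe$samples, g))
  names(des) <- genes
  tg <- stats::setNames(oe$truth$genes$transgene_probeset, genes)
  cls <- classify_effective(des, transgene_map = tg)
  list(oe = oe, des = des, cls = cls, transgene_map = tg)
}

# DE + concordance on one simulated study; returns the merged pair set.
run_concordance_study <- function(cfg, additive = TRUE, use_idmap = FALSE) {
  study <- run_full_de_study(cfg)
  tri <- simulate_trisomic_study(cfg, study$oe$truth, additive = additive)
  de_tri <- run_de(tri$expr, tri$samples, "trisomic",
                   conditions = c("trisomic", "control"))
  eff <- study$cls$gene[study$cls$label == "effective"]
  sigs <- lapply(study$des[eff], de_signature)
  if (use_idmap) {
    idmap <- simulate_id_map(cfg)
    tri_sig <- de_signature(de_tri, id_prefix = "alt_")
    cset <- map_and_merge(sigs, tri_sig, idmap)
  } else {
    cset <- map_and_merge(sigs, de_signature(de_tri))
  }
  list(study = study, cset = cset)
}
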