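#!/usr/bin/env Rscript
# Comparative C4 regulator screen: (a) induction calls on archetypal core
# carbon-shuttle enzyme profiles; (b) the three-stage TF filter (cluster
# membership, mean FPKM >= 4 in the reference, cross-species profile
# divergence vs the C3 consensus) on synthetic gradients with eight planted
# divergent regulators; (c) lineage classification of the survivors.

library(c4kit)

dir.create("results", showWarnings = FALSE)

# (a) induction assessment: a C4-style tip-induced enzyme vs the high-but-
# flat carbonic-anhydrase pattern seen in C3 leaves
cfg <- screen_config(cluster_tf_ids = sprintf("tf%04d", 1:200))
archetypes <- list(
  pepc_C4_style = c(10, 100, 400, 800),
  ca1_flat_high = c(500, 520, 495, 510),
  declining     = c(120, 60, 30, 15))
for (nm in names(archetypes)) {
  call <- assess_induction(archetypes[[nm]], cfg)
  cat(sprintf("induction[%s]: %s (tip %.0f FPKM, fold %.1f)\n",
              nm, call$induced, call$diagnostics$tip, call$diagnostics$fold))
}

# (b,c) the screen on planted data, plus recovery statistics across seeds
g <- generate_gradient(gradient_design(seed = 401))
profs <- lapply(g$datasets, mean_profiles)
cand <- suppressWarnings(tf_filter(profs, g$ortholog_map, cfg))
cat("\nStage attrition: ", paste(names(attr(cand, "attrition")),
                                 attr(cand, "attrition"),
                                 sep = "=", collapse = ", "), "\n")
print(cand[, c("gene", "category")])
cat(sprintf("Planted divergence patterns recovered: %s\n",
            setequal(cand$gene, g$truth$gene)))
write.table(cand, "results/tf_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

stats <- vapply(1:20, function(s) {
  gs <- generate_gradient(gradient_design(seed = s))
  ps <- lapply(gs$datasets, mean_profiles)
  cs <- suppressWarnings(tf_filter(ps, gs$ortholog_map, cfg))
  c(precision = ifelse(nrow(cs) == 0, NA_real_,
                       mean(cs$gene %in% gs$truth$gene)),
    recall = mean(gs$truth$gene %in% cs$gene))
}, c(precision = 0, recall = 0))
cat(sprintf("Across 20 seeds: precision = recall = 1 on %d/20\n",
            sum(stats[1, ] == 1 & stats[2, ] == 1, na.rm = TRUE)))
write.table(data.frame(seed = 1:20, t(stats)),
            "results/tf_screen_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/tf_candidates.tsv, tf_screen_recovery.tsv\n")
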