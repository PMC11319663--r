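#!/usr/bin/env Rscript
# Aggregate trial scores into condition means and FPS/APS difference
# scores, truncate outliers, and run the 2 (coil: active vs sham) x
# 2 (response type: FPS vs APS_ITI) repeated-measures ANOVA with
# post-hoc paired comparisons — the full analysis chain, driven end to
# end by run_pipeline() on a simulated 8-subject crossover study.

library(npustartle)

dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config(
  study = study_effect_spec(n_subjects = 8, coil_effect_d = 0.6),
  out_dir = "results/pipeline",
  global_seed = 20261001L
)
res <- run_pipeline(cfg)

cat("Pipeline manifest (config", attr(res$manifest, "config_hash"), "):\n")
print(res$manifest, row.names = FALSE)

for (m in names(res$anova)) {
  cat("\n==", m, "2x2 repeated-measures ANOVA ==\n")
  a <- as.data.frame(res$anova[[m]])
  a$F <- round(a$F, 3)
  a$p <- signif(a$p, 3)
  a$partial_eta_sq <- round(a$partial_eta_sq, 2)
  print(a, row.names = FALSE)
  cat("post-hoc paired comparisons:\n")
  ph <- res$posthoc[[m]]
  ph$t <- round(ph$t, 3); ph$p <- signif(ph$p, 3)
  ph$cohens_d <- round(ph$cohens_d, 3)
  ph$mean_diff <- round(ph$mean_diff, 3)
  print(ph, row.names = FALSE)
}

cat("\nNote: the generator applies the coil effect to startle only; the\n",
    "ratings coil term is null by construction, so a nominally\n",
    "significant ratings coil F at this demo sample size (n = 8) is a\n",
    "type-I error — see 04_power_calibration.R for the rejection-rate\n",
    "calibration at the study's n = 28.\n", sep = "")
cat("All stage tables written under results/pipeline/\n")
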