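#!/usr/bin/env Rscript
# Statistical stage over the whole pipeline: per-outcome condition x group
# ANOVA (Box-Cox skew gate, paper_df mode: fixed-effects on 42 session
# values, df (1, 38)) with eta-squared effect sizes, and Tukey HSD post-hoc
# comparisons. Runs the full pipeline once; all report tables land under
# results/report/.

library(gazescan)

MASTER_SEED <- 20260930L
cfg <- pipeline_config(cohort = cohort_spec(master_seed = MASTER_SEED),
                       out_dir = "results/report", seed = MASTER_SEED)
bundle <- run_pipeline(cfg)

cat("ANOVA (paper_df mode, df = (1, 38)):\n")
an <- bundle$anova
an$F <- round(an$F, 2); an$p <- signif(an$p, 3)
an$eta_sq <- round(an$eta_sq, 3)
print(an, row.names = FALSE)

cat("\nTukey HSD, eye entropy:\n")
tk <- bundle$tukey[bundle$tukey$outcome == "entropy_eye", ]
tk[2:5] <- lapply(tk[2:5], function(x) signif(x, 3))
print(tk, row.names = FALSE)

cat("\nmixed-mode comparison (condition effect on eye entropy):\n")
ent <- bundle$entropy
d <- ent[ent$effector == "eye", c("participant", "condition", "group")]
d$value <- ent$normalized[ent$effector == "eye"]
for (mode in c("paper_df", "mixed")) {
  a <- anova_condition_group(d, mode)
  cnd <- a[a$effect == "condition", ]
  cat(sprintf("  %-8s F(%d, %d) = %.2f, p = %.4g\n", mode, cnd$df_num,
              cnd$df_den, cnd$F, cnd$p))
}
cat("\nreport tables -> results/report/\n")
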