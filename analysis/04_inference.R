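#!/usr/bin/env Rscript
# Stage 4: the statistical analysis chain on the simulated survey —
# ELPD-LOO screen over the 31 metric combinations, the full cumulative
# ordinal model with evaluator random effects, 50%-acceptance thresholds
# per metric, and the rejection-reason logit.
suppressPackageStartupMessages(library(gutsgof))

seed <- 1L
dir.create("results", showWarnings = FALSE)
records <- read_survey_records("results/survey_records.csv")

cmp <- rank_predictors(records, method = "average", seed = seed)
write.csv(as.data.frame(cmp), "results/model_comparison.csv", row.names = FALSE)
cat(sprintf("screen: best of %d candidates is '%s' (ELPD %.1f, SE %.1f)\n",
            nrow(cmp), cmp$candidate[1], cmp$elpd[1], cmp$se[1]))

full <- fit_cumulative(records, method = "laplace", seed = seed + 1L)
write.csv(coef_table(full), "results/full_model_coefficients.csv", row.names = FALSE)
ct <- coef_table(full)
cat(sprintf("full model: GoF coefficient %.2f [%.2f, %.2f], evaluator SD %.2f\n",
            ct$median[ct$parameter == "avg_gof"],
            ct$lower95[ct$parameter == "avg_gof"],
            ct$upper95[ct$parameter == "avg_gof"],
            ct$median[ct$parameter == "sigma_evaluator"]))

thr <- do.call(rbind, lapply(
  c("avg_gof", "min_gof", "nrmse_s", "ppc_s", "sppe_min_s", "sppe_max_s"),
  function(m) {
    th <- acceptance_threshold(fit_acceptance_logit(records, m, seed = seed))
    data.frame(metric = m, threshold = th$threshold,
               lower = th$lower, upper = th$upper)
  }))
write.csv(thr, "results/thresholds.csv", row.names = FALSE)
cat("50% acceptance thresholds (scaled metrics):\n")
print(thr, digits = 3)

rm_fit <- fit_rejection_reason_model(records)
write.csv(rm_fit, "results/reason_model.csv", row.names = FALSE)
cat("rejection-reason model (response 1 = end-of-test-related):\n")
print(rm_fit, digits = 3)
cat("wrote results/model_comparison.csv, full_model_coefficients.csv, thresholds.csv, reason_model.csv\n")
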