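#!/usr/bin/env Rscript
# Stage 3: apply the realism filters and GoF stratification to the fit
# library, then simulate the visual-assessment survey (64 evaluators, 20
# images each in the fixed category order) from the generating score model.
suppressPackageStartupMessages(library(gutsgof))

seed <- 1L
dir.create("results", showWarnings = FALSE)

fits <- simulate_fit_library(n_fits = 30L, seed = seed)
selected <- select_fits(fits, seed = seed + 1L)
write.csv(gof_table(selected), "results/selected_fits.csv", row.names = FALSE)
cat(sprintf("%d of %d fits pass the >=70%% effect and multi-treatment filters (stratified)\n",
            length(selected), length(fits)))

truth <- true_score_model()
records <- simulate_survey(fits, truth, n_evaluators = 64L, seed = seed + 2L)
write_survey_records(records, "results/survey_records.csv")
cat(sprintf("simulated %d evaluations; acceptance rate %.2f; score distribution:\n",
            nrow(records), mean(records$accepted)))
print(table(records$score))
cat("wrote results/selected_fits.csv, results/survey_records.csv\n")
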