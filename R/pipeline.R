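#' Pipeline configuration
#'
#' Stage-scoped seeds and scale settings for [run_pipeline()]. All
#' randomness flows through these seeds; identical configuration gives
#' identical outputs.
#'
#' @param seed master seed; stage seeds derive from it unless given.
#' @param n_fits size of the synthetic fit library.
#' @param n_evaluators evaluator pool size.
#' @param truth the generating [true_score_model()].
#' @param calibrate run a full MCMC calibration demo on one synthetic
#'   dataset (slowest stage; skippable).
#' @param screen_method combination rule used in the predictor screen.
#' @param full_model_method `"laplace"` (fast) or `"mcmc"` for the full
#'   ordinal model.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_fits = 30L, n_evaluators = 64L,
                            truth = true_score_model(), calibrate = TRUE,
                            screen_method = "average",
                            full_model_method = "laplace",
                            out_dir = "results") {
  structure(list(seed = as.integer(seed), n_fits = n_fits,
                 n_evaluators = n_evaluators, truth = truth,
                 calibrate = calibrate, screen_method = screen_method,
                 full_model_method = full_model_method, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain generate-fits, (optional) calibrate, GoF,
#' select, survey simulation, and inference, writing each artifact as CSV
#' or JSON under the configured output directory together with a manifest
#' (stage seeds, warnings, and an MD5 of the configuration). A stage
#' failure aborts with the stage name; artifacts written so far persist.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the in-memory artifacts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(fits = config$seed, calibrate = config$seed + 1000L,
                survey = config$seed + 2000L, inference = config$seed + 3000L)
  manifest <- list(seeds = seeds, warnings = character(), stages = character())
  art <- list()
  stage <- function(name, expr) {
    message(sprintf("[pipeline] stage %s", name))
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  art$fits <- stage("generate-fits",
    simulate_fit_library(config$n_fits, seed = seeds$fits))
  art$gof <- stage("gof", gof_table(art$fits))
  utils::write.csv(art$gof, file.path(config$out_dir, "fits_gof.csv"),
                   row.names = FALSE)

  if (config$calibrate) {
    art$calibration <- stage("calibrate", {
      true <- guts_params_sd(hb = 0.02, kd = 0.8, z = 1.0, b = 0.3)
      ds <- simulate_survival_dataset(true, seed = seeds$calibrate)
      post <- fit_posterior(ds, "SD", seed = seeds$calibrate)
      write_posterior_csv(post, file.path(config$out_dir, "calibration_draws.csv"))
      list(true = true, dataset = ds, posterior = post)
    })
  }

  art$selected <- stage("select",
    select_fits(art$fits, seed = seeds$fits + 1L, stratify = TRUE))
  utils::write.csv(gof_table(art$selected),
                   file.path(config$out_dir, "selected_fits.csv"), row.names = FALSE)

  art$records <- stage("survey-sim",
    simulate_survey(art$fits, truth = config$truth,
                    n_evaluators = config$n_evaluators, seed = seeds$survey))
  write_survey_records(art$records,
                       file.path(config$out_dir, "survey_records.csv"))

  art$screen <- stage("screen",
    rank_predictors(art$records, method = config$screen_method,
                    seed = seeds$inference))
  utils::write.csv(as.data.frame(art$screen),
                   file.path(config$out_dir, "model_comparison.csv"),
                   row.names = FALSE)

  art$full_model <- stage("full-model",
    fit_cumulative(art$records, gof_var = config$truth$gof_var,
                   method = config$full_model_method,
                   seed = seeds$inference + 1L))
  utils::write.csv(coef_table(art$full_model),
                   file.path(config$out_dir, "full_model_coefficients.csv"),
                   row.names = FALSE)

  art$thresholds <- stage("thresholds", {
    metrics <- c("avg_gof", "min_gof", "nrmse_s", "ppc_s", "sppe_min_s", "sppe_max_s")
    do.call(rbind, lapply(metrics, function(m) {
      fit <- fit_acceptance_logit(art$records, m, seed = seeds$inference + 2L)
      th <- acceptance_threshold(fit)
      data.frame(metric = m, threshold = th$threshold, lower = th$lower,
                 upper = th$upper, flagged = !is.null(th$flag))
    }))
  })
  utils::write.csv(art$thresholds, file.path(config$out_dir, "thresholds.csv"),
                   row.names = FALSE)

  art$reason_model <- stage("reason-model",
    fit_rejection_reason_model(art$records))
  utils::write.csv(art$reason_model,
                   file.path(config$out_dir, "reason_model.csv"), row.names = FALSE)

  art$representation <- stage("representation", {
    cmp <- compare_representations(art$records)
    glmfit <- fit_representation_acceptance(art$records,
                                            seed = seeds$inference + 3L)
    utils::write.csv(cmp$per_fit,
                     file.path(config$out_dir, "representation_per_fit.csv"),
                     row.names = FALSE)
    list(comparison = cmp, acceptance = glmfit)
  })

  art$panels <- stage("panels", {
    f <- art$selected[[1]] %||% art$fits[[1]]
    ts <- build_timeseries_panels(f$dataset, f$summary,
                                  image_id = paste0(f$fit_id, "_TS"),
                                  fit_id = f$fit_id)
    drc <- build_drc_panels(f$dataset, f$posterior,
                            image_id = paste0(f$fit_id, "_DRC"),
                            fit_id = f$fit_id, seed = seeds$fits + 2L)
    write_image_json(ts, file.path(config$out_dir, "example_panels_ts.json"))
    write_image_json(drc, file.path(config$out_dir, "example_panels_drc.json"))
    list(ts = ts, drc = drc)
  })

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_json <- jsonlite::toJSON(list(seed = config$seed, n_fits = config$n_fits,
                                    n_evaluators = config$n_evaluators,
                                    screen_method = config$screen_method,
                                    full_model_method = config$full_model_method),
                               auto_unbox = TRUE)
  writeLines(cfg_json, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(art)
}
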