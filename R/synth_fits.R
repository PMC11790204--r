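#' Simulate a survival dataset from known GUTS parameters
#'
#' Generates constant-exposure treatments (a control plus a geometric
#' concentration series), computes the true survival curves and draws
#' survivor counts by conditional binomial sampling. This is the forward
#' model used throughout for parameter-recovery checks.
#'
#' @param params true [guts_params_sd()] or [guts_params_it()].
#' @param concentrations exposure concentration per treatment (0 = control).
#' @param n0 organisms per treatment.
#' @param obs_times observation times (days), starting at 0.
#' @param seed integer seed.
#' @param role dataset role.
#' @param id dataset label.
#' @return a [survival_dataset()] with one experiment.
#' @export
simulate_survival_dataset <- function(params, concentrations = c(0, 0.5, 1, 2, 4),
                                      n0 = 50L, obs_times = 0:7, seed = 1L,
                                      role = "calibration", id = "sim") {
  trts <- lapply(seq_along(concentrations), function(i) {
    prof <- exposure_profile(0, concentrations[i])
    curve <- predict_survival(prof, params, obs_times)
    counts <- sample_survival_counts(curve, n0, seed = seed + i)
    treatment(id = sprintf("T%d", i), profile = prof,
              obs_times = obs_times, survivors = counts, n0 = n0)
  })
  survival_dataset(list(trts), role = role, id = id)
}

# pseudo-posterior centred on a parameter set: lognormal jitter on the
# toxicity parameters, used by the fit-library generator where a full MCMC
# per fit would add nothing to the downstream survey analysis
pseudo_posterior <- function(params, variant, n_draws = 150L, spread = 0.08,
                             seed = 1L) {
  nat <- unlist(params[c("hb", "kd",
                         if (variant == "SD") c("z", "b") else c("mw", "beta"))])
  draws <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_draws * 4, 0, spread), n_draws, 4)
    m[, 1] <- m[, 1] * 0.5   # keep background hazard tight
    sweep(exp(m), 2, nat, `*`)
  })
  colnames(draws) <- names(nat)
  structure(list(variant = variant, draws = draws,
                 log_lik = rep(NA_real_, n_draws),
                 diagnostics = list(rhat = rep(1, 4), ess = rep(n_draws, 4),
                                    accept = NA, converged = TRUE),
                 seed = seed),
            class = "guts_posterior")
}

#' Parameter-recovery study dataset
#'
#' The package's canonical design for checking that calibration recovers
#' known GUTS-RED-SD parameters: five treatments of `n0` organisms observed
#' at seven times over 14 days — a control, constant exposures at 1.5x, 3x
#' and 6x the damage threshold, and a 1.5-day depuration pulse at 5x. The
#' mix identifies `kd` (early onset and pulse decay), `z` (onset
#' concentration dependence) and `b` (sustained kill rates at two exceedance
#' levels) jointly, mirroring the variety of acute/chronic and
#' constant/pulsed exposures in real dataset collections.
#'
#' @param params true [guts_params_sd()].
#' @param n0 organisms per treatment.
#' @param seed integer seed.
#' @return a [survival_dataset()] with one experiment of five treatments.
#' @export
simulate_recovery_dataset <- function(params = guts_params_sd(0.02, 0.8, 1, 0.3),
                                      n0 = 50L, seed = 1L) {
  z <- params$z
  obs <- c(0, 0.5, 1, 2, 4, 7, 14)
  profs <- list(
    exposure_profile(0, 0),
    exposure_profile(0, 1.5 * z),
    exposure_profile(0, 3 * z),
    exposure_profile(0, 6 * z),
    exposure_profile(c(0, 1.5, 1.501, 14), c(5 * z, 5 * z, 0, 0)))
  trts <- lapply(seq_along(profs), function(i) {
    curve <- survival_sd(profs[[i]], params, obs)
    counts <- sample_survival_counts(curve, n0, seed = seed * 37L + i)
    treatment(sprintf("T%d", i), profs[[i]], obs, counts, n0)
  })
  survival_dataset(list(trts), id = "recovery")
}

#' Generate a library of model fits with graded quality
#'
#' Emulates the pool of calibration/validation fits offered for visual
#' evaluation: each fit is a synthetic toxicity dataset generated from known
#' SD parameters, paired with predictions from a quality-degraded parameter
#' set (log-scale perturbation whose magnitude is drawn per fit), so that
#' the library spans the whole range of goodness of fit. Each fit carries
#' its dataset, a pseudo-posterior around the (perturbed) prediction
#' parameters, a posterior-predictive summary, the paired series and the
#' full [gof_metrics()].
#'
#' @param n_fits number of fits.
#' @param seed integer seed.
#' @param n0 organisms per treatment.
#' @param obs_times observation times (days).
#' @param max_quality_spread largest log-scale perturbation SD of the
#'   prediction parameters (worst fits).
#' @return list of fit objects (`fit_id`, `role`, `dataset`, `posterior`,
#'   `summary`, `paired`, `gof`, `end_mortality`, `true_params`,
#'   `pred_params`).
#' @export
simulate_fit_library <- function(n_fits = 30L, seed = 1L, n0 = 20L,
                                 obs_times = 0:5, max_quality_spread = 1.6) {
  meta <- with_seed(seed, {
    data.frame(
      kd = exp(stats::rnorm(n_fits, log(0.8), 0.4)),
      z = exp(stats::rnorm(n_fits, 0, 0.4)),
      b = exp(stats::rnorm(n_fits, log(0.6), 0.4)),
      n_treat = sample(3:5, n_fits, replace = TRUE),
      n_exp = sample(1:2, n_fits, replace = TRUE, prob = c(0.6, 0.4)),
      quality = stats::runif(n_fits, 0.02, max_quality_spread),
      pshift = stats::rnorm(n_fits * 3)[seq_len(n_fits)])
  })
  lapply(seq_len(n_fits), function(i) {
    true <- guts_params_sd(hb = 0.02, kd = meta$kd[i], z = meta$z[i], b = meta$b[i])
    experiments <- lapply(seq_len(meta$n_exp[i]), function(ex) {
      concs <- c(0, meta$z[i] * 2^seq(-1, 3, length.out = meta$n_treat[i] - 1))
      lapply(seq_along(concs), function(k) {
        prof <- exposure_profile(0, concs[k])
        curve <- predict_survival(prof, true, obs_times)
        counts <- sample_survival_counts(curve, n0, seed = seed + 7919L * i + 131L * ex + k)
        treatment(sprintf("E%dT%d", ex, k), prof, obs_times, counts, n0)
      })
    })
    ds <- survival_dataset(experiments,
                           role = if (i %% 2 == 0) "validation" else "calibration",
                           id = sprintf("fit%03d", i))
    pred_pars <- with_seed(seed + 104729L * i, {
      eps <- stats::rnorm(3, 0, meta$quality[i])
      guts_params_sd(hb = true$hb, kd = true$kd * exp(eps[1]),
                     z = true$z * exp(eps[2]), b = true$b * exp(eps[3]))
    })
    post <- pseudo_posterior(pred_pars, "SD", seed = seed + 224737L * i)
    summ <- predict_summary(ds, post, include_sampling_error = TRUE,
                            n_draws = nrow(post$draws), seed = seed + i)
    paired <- paired_series(summ)
    gof <- gof_metrics(paired)
    trs <- all_treatments(ds)
    list(fit_id = ds$id, role = ds$role, dataset = ds, posterior = post,
         summary = summ, paired = paired, gof = gof,
         end_mortality = vapply(trs, function(tr)
           1 - tr$survivors[length(tr$survivors)] / tr$n0, numeric(1)),
         true_params = true, pred_params = pred_pars)
  })
}

#' One-row-per-fit table of raw, scaled and combined GoF metrics
#' @param fits a fit library (see [simulate_fit_library()]).
#' @return data frame with raw metrics, scaled metrics and combined GoF.
#' @export
gof_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    g <- f$gof
    data.frame(fit_id = f$fit_id, role = f$role,
               nrmse = g$raw$nrmse, ppc = g$raw$ppc,
               sppe_min = g$raw$sppe_min, sppe_max = g$raw$sppe_max,
               pseudo_r2 = g$raw$pseudo_r2,
               nrmse_s = unname(g$scaled["nrmse"]), ppc_s = unname(g$scaled["ppc"]),
               sppe_min_s = unname(g$scaled["sppe_min"]),
               sppe_max_s = unname(g$scaled["sppe_max"]),
               pseudo_r2_s = unname(g$scaled["pseudo_r2"]),
               avg_gof = g$avg_gof, min_gof = g$min_gof)
  }))
}
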