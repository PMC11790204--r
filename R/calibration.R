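#' Sampler settings for GUTS calibration
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain (50% discarded as burn-in).
#' @param thin thinning interval of the retained draws.
#' @param hb_max upper bound of the uniform background-hazard prior (1/day).
#' @param kd_bounds,b_bounds,beta_bounds log-uniform prior bounds.
#' @param threshold_bounds bounds for `z` (SD) / `mw` (IT); `NULL` derives
#'   them from the tested concentrations as
#'   `[1e-2 * min positive, 10 * max]`.
#' @return a list of sampler settings.
#' @export
calibration_control <- function(n_chains = 4L, n_iter = 2000L, thin = 2L,
                                hb_max = 0.1,
                                kd_bounds = c(1e-3, 1e2),
                                b_bounds = c(1e-4, 1e3),
                                beta_bounds = c(0.1, 30),
                                threshold_bounds = NULL) {
  list(n_chains = n_chains, n_iter = n_iter, thin = thin, hb_max = hb_max,
       kd_bounds = kd_bounds, b_bounds = b_bounds, beta_bounds = beta_bounds,
       threshold_bounds = threshold_bounds)
}

dataset_conc_range <- function(dataset) {
  conc <- unlist(lapply(all_treatments(dataset),
                        function(tr) tr$profile$concentrations))
  pos <- conc[conc > 0]
  if (length(pos) == 0) return(NULL)
  c(min(pos), max(pos))
}

make_params <- function(variant, th) {
  # th on natural scale: (hb, kd, threshold, rate/shape)
  if (variant == "SD") guts_params_sd(th[1], th[2], th[3], th[4])
  else guts_params_it(th[1], th[2], th[3], th[4])
}

#' Bayesian calibration of a GUTS-RED variant
#'
#' Samples the posterior of (`hb`, `kd`, `z`, `b`) (SD) or
#' (`hb`, `kd`, `mw`, `beta`) (IT) under the conditional-binomial likelihood
#' with independent log-uniform priors on the toxicity parameters (bounds in
#' [calibration_control()]; the threshold range is derived from the tested
#' concentrations unless given) and a uniform prior on `hb`. Sampling uses
#' an adaptive random-walk Metropolis on the log-parameter scale; split-Rhat
#' and effective sample size are recorded per parameter, and Rhat > 1.05 is
#' flagged (not fatal). Identical seed, settings and data give bit-identical
#' draws.
#'
#' @param dataset a [survival_dataset()] with at least one exposed treatment.
#' @param variant `"SD"` or `"IT"`.
#' @param control a [calibration_control()].
#' @param seed integer seed.
#' @return object of class `guts_posterior`: `draws` (natural-scale matrix),
#'   `log_lik` per draw, `diagnostics` (`rhat`, `ess`, `accept`,
#'   `converged`), `variant`, `seed`.
#' @export
fit_posterior <- function(dataset, variant = c("SD", "IT"),
                          control = calibration_control(), seed = 1L) {
  variant <- match.arg(variant)
  assert_that(inherits(dataset, "survival_dataset"), "dataset must be a survival_dataset")
  trs <- all_treatments(dataset)
  assert_that(any(vapply(trs, function(tr) length(tr$obs_times) >= 2, logical(1))),
              "need at least one treatment with >= 2 time points")
  cr <- dataset_conc_range(dataset)
  if (is.null(cr)) stop("toxicity parameters unidentifiable: no exposed treatment in dataset",
                        call. = FALSE)
  thb <- control$threshold_bounds %||% c(1e-2 * cr[1], 10 * cr[2])
  rb <- if (variant == "SD") control$b_bounds else control$beta_bounds
  lb <- log(c(1e-8, control$kd_bounds[1], thb[1], rb[1]))
  ub <- log(c(control$hb_max, control$kd_bounds[2], thb[2], rb[2]))

  log_prior <- function(theta) {
    if (any(theta < lb) || any(theta > ub)) return(-Inf)
    theta[1]  # uniform on natural hb => Jacobian log(hb); log-uniform elsewhere
  }
  log_post <- function(theta) {
    lp <- log_prior(theta)
    if (!is.finite(lp)) return(-Inf)
    ll <- log_likelihood(dataset, make_params(variant, exp(theta)))
    if (!is.finite(ll)) return(-Inf)
    ll + lp
  }
  init <- log(c(0.01, 0.5,
                exp(mean(log(thb))),
                if (variant == "SD") 1 / cr[2] else 2))
  init <- pmin(pmax(init, lb + 0.5), ub - 0.5)
  res <- run_metropolis(log_post, init, n_chains = control$n_chains,
                        n_iter = control$n_iter, thin = control$thin,
                        seed = seed)
  draws <- exp(res$draws)
  colnames(draws) <- if (variant == "SD") c("hb", "kd", "z", "b")
                     else c("hb", "kd", "mw", "beta")
  rhat <- split_rhat(res$chains)
  ess <- ess_basic(res$chains)
  names(rhat) <- names(ess) <- colnames(draws)
  log_lik <- res$lp_all - res$draws[, 1]   # subtract the hb Jacobian term
  structure(list(
    variant = variant, draws = draws, log_lik = log_lik,
    diagnostics = list(rhat = rhat, ess = ess, accept = res$accept,
                       converged = all(rhat < 1.05)),
    bounds = list(lower = exp(lb), upper = exp(ub)),
    seed = seed, control = control, dataset_id = dataset$id),
    class = "guts_posterior")
}

#' @export
print.guts_posterior <- function(x, ...) {
  cat(sprintf("<guts_posterior> GUTS-RED-%s, %d draws, max Rhat %.3f%s\n",
              x$variant, nrow(x$draws), max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "" else " (NOT converged)"))
  print(round(t(apply(x$draws, 2, stats::quantile, c(0.025, 0.5, 0.975))), 4))
  invisible(x)
}

#' Posterior medians as a parameter object
#' @param posterior a `guts_posterior`.
#' @return a [guts_params_sd()] or [guts_params_it()] at the posterior medians.
#' @export
posterior_median_params <- function(posterior) {
  med <- apply(posterior$draws, 2, stats::median)
  make_params(posterior$variant, med)
}

#' Posterior predictive summary per treatment and observation time
#'
#' For each retained draw, survival probabilities are computed at the
#' observation times of every treatment; predicted survivor counts are
#' either `n0 * S` (parameter uncertainty only) or a fresh binomial draw
#' (posterior predictive, the default, matching the survivor count being an
#' integer observable). Medians and 2.5%/97.5% quantiles are reported.
#'
#' @param dataset a [survival_dataset()].
#' @param posterior a `guts_posterior` (or a one-row draw matrix wrapped in one).
#' @param include_sampling_error include binomial sampling error in the
#'   predictive interval (default `TRUE`).
#' @param n_draws number of posterior draws to use; if more than available,
#'   draws are resampled with replacement with a warning.
#' @param seed integer seed for draw subsampling and binomial resampling.
#' @return a `prediction_summary`: data frame with `experiment`, `treatment`,
#'   `time`, `n0`, `obs`, `lower`, `median`, `upper` (counts) and `s_median`
#'   (survival probability).
#' @export
predict_summary <- function(dataset, posterior, include_sampling_error = TRUE,
                            n_draws = 500L, seed = 1L) {
  assert_that(nrow(posterior$draws) >= 1L, "posterior is empty")
  n_avail <- nrow(posterior$draws)
  idx <- with_seed(seed, {
    if (n_draws > n_avail) {
      warning("n_draws exceeds available draws; sampling with replacement")
      sample.int(n_avail, n_draws, replace = TRUE)
    } else if (n_draws == n_avail) seq_len(n_avail)
    else sample.int(n_avail, n_draws)
  })
  rows <- list()
  rng_seed <- seed + 1L
  for (ex_i in seq_along(dataset$experiments)) {
    for (tr in dataset$experiments[[ex_i]]) {
      S <- matrix(0, length(idx), length(tr$obs_times))
      for (k in seq_along(idx)) {
        pars <- make_params(posterior$variant, posterior$draws[idx[k], ])
        S[k, ] <- predict_survival(tr$profile, pars, tr$obs_times)$probabilities
      }
      counts <- if (include_sampling_error) {
        with_seed(rng_seed, matrix(stats::rbinom(length(S), tr$n0, as.numeric(S)),
                                   nrow(S), ncol(S)))
      } else tr$n0 * S
      rng_seed <- rng_seed + 1L
      qs <- apply(counts, 2, stats::quantile, c(0.025, 0.5, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = ex_i, treatment = tr$id, time = tr$obs_times, n0 = tr$n0,
        obs = tr$survivors,
        lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
        s_median = apply(S, 2, stats::median))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_summary", "data.frame")
  out
}

#' Write posterior draws to CSV (one row per draw)
#' @param posterior a `guts_posterior`.
#' @param path output path.
#' @export
write_posterior_csv <- function(posterior, path) {
  df <- as.data.frame(posterior$draws)
  df$log_lik <- posterior$log_lik
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
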