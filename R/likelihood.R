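predict_survival <- function(profile, params, times) {
  if (inherits(params, "guts_params_sd")) survival_sd(profile, params, times)
  else survival_it(profile, params, times)
}

#' Conditional-binomial log-likelihood of survival counts
#'
#' The standard GUTS calibration likelihood: deaths between consecutive
#' observation times are binomial with the conditional survival probability
#' `S(t_j) / S(t_{j-1})`, which makes the death pattern per treatment
#' multinomial. Ratios are clamped to `[1e-12, 1]` before the log; a
#' predicted survival of exactly zero with survivors still observed yields
#' `-Inf` (not an error).
#'
#' @param dataset a [survival_dataset()].
#' @param params a [guts_params_sd()] or [guts_params_it()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params) {
  assert_that(inherits(dataset, "survival_dataset"), "dataset must be a survival_dataset")
  ll <- 0
  for (tr in all_treatments(dataset)) {
    S <- predict_survival(tr$profile, params, tr$obs_times)$probabilities
    y <- tr$survivors
    for (j in seq_along(y)[-1]) {
      if (S[j] == 0 && y[j] > 0) return(-Inf)
      ratio <- if (S[j - 1] <= 0) 0 else S[j] / S[j - 1]
      ratio <- min(max(ratio, 1e-12), 1)
      ll <- ll + stats::dbinom(y[j], y[j - 1], ratio, log = TRUE)
    }
  }
  ll
}
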