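logit_sims <- function(coefs, vc, n_sims, seed) {
  L <- t(chol(vc + diag(1e-12, nrow(vc))))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_sims * length(coefs)), ncol = length(coefs))
    sims <- t(coefs + L %*% t(z))
    colnames(sims) <- names(coefs)
    sims
  })
}

check_separation <- function(fit) {
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop(paste("complete (or quasi-complete) separation detected;",
               sprintf("outcome split %s over %d records",
                       paste(table(fit$y), collapse = "/"), length(fit$y))),
         call. = FALSE)
}

#' Bernoulli-logit model of fit acceptance vs a GoF metric
#'
#' Acceptance is scores 1-3, non-acceptance 4-6. The acceptance probability
#' is `logit^-1(a + b * metric)`. Estimated by maximum likelihood
#' ([stats::glm()]); the coefficient sampling distribution (normal
#' approximation) is stored for interval computations.
#'
#' @param records survey records with `score` and the predictor column.
#' @param predictor name of the metric column (e.g. `"avg_gof"`).
#' @param n_sims coefficient draws kept for intervals.
#' @param seed integer seed for those draws.
#' @return object of class `logit_fit` with `coef` (`a`, `b`), `vcov`,
#'   `sims`, `n`.
#' @export
fit_acceptance_logit <- function(records, predictor = "avg_gof",
                                 n_sims = 4000L, seed = 1L) {
  assert_that(predictor %in% names(records),
              sprintf("records lack column '%s'", predictor))
  y <- records$score <= 3L
  assert_that(any(y) && any(!y), "both acceptance outcomes must be present")
  x <- records[[predictor]]
  assert_that(length(unique(x)) >= 2, "predictor must take >= 2 distinct values")
  fit <- stats::glm(y ~ x, family = stats::binomial())
  check_separation(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- c("a", "b")
  vc <- stats::vcov(fit)
  structure(list(predictor = predictor, coef = coefs, vcov = vc,
                 sims = logit_sims(coefs, vc, n_sims, seed),
                 fitted = stats::fitted(fit), n = length(y), glm = fit),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> accept ~ %s: a = %.3f, b = %.3f (n = %d)\n",
              x$predictor, x$coef["a"], x$coef["b"], x$n))
  invisible(x)
}

#' Metric value at which 50% of evaluators accept the fit
#'
#' The 50%-acceptance threshold of a fitted acceptance logit is the root of
#' the linear predictor, `-a/b`; its uncertainty is summarized by the median
#' and 95% interval of `-a/b` over the stored coefficient draws. A
#' non-positive slope or a threshold outside `[range]` is flagged (field
#' `flag`), not silently returned.
#'
#' @param fit a `logit_fit`.
#' @param range valid metric range used for the flag (default `[0, 1]`).
#' @return list `threshold` (point estimate `-a/b`), `median`, `lower`,
#'   `upper`, `flag`.
#' @export
acceptance_threshold <- function(fit, range = c(0, 1)) {
  th <- -fit$coef["a"] / fit$coef["b"]
  sims_th <- -fit$sims[, "a"] / fit$sims[, "b"]
  sims_th <- sims_th[is.finite(sims_th)]
  flag <- NULL
  if (fit$coef["b"] <= 0) flag <- "non-positive slope: metric does not increase acceptance"
  else if (th < range[1] || th > range[2])
    flag <- sprintf("threshold %.3f outside the metric range [%g, %g]", th, range[1], range[2])
  if (!is.null(flag)) warning(flag)
  qs <- stats::quantile(sims_th, c(0.5, 0.025, 0.975), names = FALSE)
  list(threshold = unname(th), median = qs[1], lower = qs[2], upper = qs[3],
       flag = flag)
}

#' Logit model of the rejection-reason group on the four scaled metrics
#'
#' Uses only non-accepted time-series records (score 4-6) whose reason falls
#' in the grouped letters a-d. Response 1 = end-of-test-related reason (a or
#' b), 0 = time-course-related (c or d); predictors are the scaled
#' `sppe_min`, `sppe_max`, `nrmse` and `ppc`. A negative coefficient means
#' the metric, in line with the evaluators, judges a fit bad because of
#' mismatch at the end of the toxicity test; a positive one, mismatch along
#' the time course.
#'
#' @param records survey records with `score`, `reasons` and the scaled
#'   metric columns.
#' @return data frame (intercept + 4 coefficients) with estimate, SE and
#'   95% interval, plus attributes `n` and `glm`.
#' @export
fit_rejection_reason_model <- function(records) {
  use <- records$score >= 4L & records$reasons %in% REASONS_TS
  r <- records[use, , drop = FALSE]
  assert_that(nrow(r) >= 2, "need rejected time-series records with grouped reasons")
  y <- as.numeric(r$reasons %in% c("a", "b"))
  assert_that(any(y == 1) && any(y == 0),
              "both reason groups must be present")
  for (nm in c("sppe_min_s", "sppe_max_s", "nrmse_s", "ppc_s"))
    assert_that(stats::sd(r[[nm]]) > 0, sprintf("metric column %s constant", nm))
  fit <- stats::glm(y ~ sppe_min_s + sppe_max_s + nrmse_s + ppc_s,
                    data = r, family = stats::binomial())
  check_separation(fit)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = c("intercept", "sppe_min", "sppe_max", "nrmse", "ppc"),
                    estimate = sm[, 1], se = sm[, 2],
                    lower95 = sm[, 1] - stats::qnorm(0.975) * sm[, 2],
                    upper95 = sm[, 1] + stats::qnorm(0.975) * sm[, 2],
                    row.names = NULL)
  attr(out, "n") <- nrow(r)
  attr(out, "glm") <- fit
  out
}

#' Logit model of acceptance on the representation type
#'
#' Acceptance (score 1-3) modelled on the presentation as dose-response
#' curve vs time series; the reported coefficient is the DRC effect (log
#' odds ratio vs TS).
#'
#' @param records survey records with `score` and `representation`.
#' @param n_sims coefficient draws kept for intervals.
#' @param seed integer seed for those draws.
#' @return a `logit_fit` whose slope is the DRC indicator coefficient.
#' @export
fit_representation_acceptance <- function(records, n_sims = 4000L, seed = 1L) {
  assert_that(all(c("TS", "DRC") %in% records$representation),
              "both representations must be present")
  y <- records$score <= 3L
  x <- as.numeric(records$representation == "DRC")
  fit <- stats::glm(y ~ x, family = stats::binomial())
  check_separation(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- c("a", "b")
  structure(list(predictor = "representation_DRC", coef = coefs,
                 vcov = stats::vcov(fit),
                 sims = logit_sims(coefs, stats::vcov(fit), n_sims, seed),
                 fitted = stats::fitted(fit), n = length(y), glm = fit),
            class = "logit_fit")
}
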