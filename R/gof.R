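#' Paired observed/predicted series for GoF computation
#'
#' Pairs every observation with its prediction and 95% predictive interval.
#' Rows at `t = 0` (where the prediction is exactly `n0`) are dropped by
#' default: they carry no information about fit quality and would inflate
#' the PPC and deflate the NRMSE.
#'
#' @param summary a [predict_summary()] result (needs `obs`, `median`,
#'   `lower`, `upper`, `n0`, `time`, `treatment`), or a data frame with the
#'   same columns.
#' @param drop_t0 drop the `t = 0` rows (default `TRUE`).
#' @return object of class `paired_series` (a data frame).
#' @export
paired_series <- function(summary, drop_t0 = TRUE) {
  need <- c("treatment", "time", "obs", "median", "lower", "upper", "n0")
  assert_that(all(need %in% names(summary)),
              paste("paired series needs columns", paste(need, collapse = ",")))
  df <- as.data.frame(summary)[, c(need, intersect("s_median", names(summary)))]
  names(df)[names(df) == "median"] <- "pred"
  if (drop_t0) df <- df[df$time > 0, , drop = FALSE]
  assert_that(nrow(df) >= 1L, "paired series needs at least one entry")
  class(df) <- c("paired_series", "data.frame")
  df
}

#' Normalised root-mean-square error (%)
#'
#' `100 / Ybar * sqrt(mean((y_obs - y_pred)^2))`, where `Ybar` is the mean
#' observed survivor count across all entries; aggregates prediction error
#' over time points and treatments.
#'
#' @param paired a [paired_series()].
#' @return NRMSE in percent (`>= 0`).
#' @export
nrmse <- function(paired) {
  ybar <- mean(paired$obs)
  if (ybar <= 0) stop("normalization undefined: mean observed survivors is 0",
                      call. = FALSE)
  100 / ybar * sqrt(mean((paired$obs - paired$pred)^2))
}

#' Survival probability prediction error at the end of the test (%)
#'
#' Per treatment `k`, `SPPE_k = 100 * (y_end_obs - y_end_pred) / n0`. The
#' two summary indices clip at zero: `sppe_min = min(min_k SPPE_k, 0)`
#' (largest underestimation of effects) and `sppe_max = max(max_k SPPE_k, 0)`
#' (largest overestimation); when all treatments err in the same direction,
#' the opposite index is 0% because there is no error in that direction.
#'
#' @param y_end_obs,y_end_pred observed / predicted survivors at the last
#'   count, one per treatment.
#' @param n0 tested organisms per treatment.
#' @return list with `sppe_min`, `sppe_max`, `per_treatment`.
#' @export
sppe <- function(y_end_obs, y_end_pred, n0) {
  assert_that(length(y_end_obs) >= 1L, "need at least one treatment")
  assert_that(all(n0 >= 1), "n0 must be >= 1 in every treatment")
  per <- 100 * (y_end_obs - y_end_pred) / n0
  list(sppe_min = min(min(per), 0), sppe_max = max(max(per), 0),
       per_treatment = per)
}

#' Posterior predictive check (%)
#'
#' Percentage of observations falling inside their 95% predictive credible
#' interval; interval bounds count as inside (closed-interval indicator).
#'
#' @param paired a [paired_series()] with `lower`/`upper` bounds.
#' @return PPC in percent, in `[0, 100]`.
#' @export
ppc <- function(paired) {
  assert_that(!any(is.na(paired$lower)) && !any(is.na(paired$upper)),
              "PPC requires credible-interval bounds for every entry")
  100 * mean(paired$obs >= paired$lower & paired$obs <= paired$upper)
}

#' Nagelkerke pseudo-R-squared at end-of-test counts
#'
#' Compares the binomial likelihood of the fitted model (`LM`, at the
#' predicted end survival probabilities) with a null model that assumes one
#' average survival probability — the ratio of total survivors to total
#' tested organisms across treatments:
#' `R2 = (1 - (L0/LM)^(2/n)) / (1 - L0^(2/n))`, `n` the number of treatments.
#'
#' @param y_end_obs observed survivors at the last count, per treatment.
#' @param n0 tested organisms per treatment.
#' @param p_pred_end predicted end survival probability per treatment.
#' @return pseudo-R-squared (`<= 1`).
#' @export
nagelkerke_r2 <- function(y_end_obs, n0, p_pred_end) {
  n <- length(y_end_obs)
  assert_that(n >= 1L, "need at least one treatment")
  assert_that(all(p_pred_end >= 0 & p_pred_end <= 1), "p_pred_end must lie in [0,1]")
  p0 <- sum(y_end_obs) / sum(n0)
  logL0 <- sum(stats::dbinom(y_end_obs, n0, p0, log = TRUE))
  logLM <- sum(stats::dbinom(y_end_obs, n0, p_pred_end, log = TRUE))
  if (logL0 >= 0) stop("null model saturated", call. = FALSE)
  if (!is.finite(logLM)) {
    warning("model likelihood is zero; pseudo-R2 is -Inf")
    return(-Inf)
  }
  (1 - exp(2 / n * (logL0 - logLM))) / (1 - exp(2 / n * logL0))
}

#' Rescale a raw GoF metric to the unit interval
#'
#' Metrics where lower raw values mean better performance (NRMSE, SPPE) are
#' inverted so that 1 always means best: `ppc -> value/100`,
#' `nrmse -> max(0, 1 - value/100)`, `sppe_min`/`sppe_max ->
#' max(0, 1 - |value|/100)`, `pseudo_r2 -> max(0, value)`.
#'
#' @param name one of `"nrmse"`, `"ppc"`, `"sppe_min"`, `"sppe_max"`,
#'   `"pseudo_r2"`.
#' @param value raw metric value.
#' @return scaled value in `[0, 1]`.
#' @export
scale_metric <- function(name, value) {
  switch(name,
    ppc = value / 100,
    nrmse = pmin(1, pmax(0, 1 - value / 100)),
    sppe_min = ,
    sppe_max = pmax(0, 1 - abs(value) / 100),
    pseudo_r2 = pmin(1, pmax(0, value)),
    stop(sprintf("unknown metric '%s'", name), call. = FALSE))
}

#' Combine scaled metrics into a single GoF value
#'
#' The "average GoF" (standard scientific reading) is the arithmetic mean of
#' the selected scaled metrics; the "minimum GoF" (regulatory, conservative
#' reading) is their minimum. The default member set is NRMSE, PPC,
#' SPPE_min and SPPE_max.
#'
#' @param scaled named numeric vector/list of scaled metrics in `[0, 1]`.
#' @param method `"average"` or `"minimum"`.
#' @param members metric names to combine.
#' @return combined GoF in `[0, 1]`.
#' @export
combine_gof <- function(scaled, method = c("average", "minimum"),
                        members = c("nrmse", "ppc", "sppe_min", "sppe_max")) {
  method <- match.arg(method)
  assert_that(length(members) >= 1L, "members must be non-empty")
  scaled <- unlist(scaled)
  missing <- setdiff(members, names(scaled))
  assert_that(length(missing) == 0,
              paste("missing scaled metrics:", paste(missing, collapse = ",")))
  v <- scaled[members]
  if (method == "average") mean(v) else min(v)
}

#' All GoF metrics for one fit
#'
#' Computes the five raw metrics, their `[0, 1]` rescalings, and the
#' average/minimum combined GoF from a paired series plus end-of-test data.
#'
#' @param paired a [paired_series()].
#' @param end data frame with one row per treatment: `obs_end`, `pred_end`,
#'   `n0`, `p_pred_end`. If `NULL`, derived from the last time point of each
#'   treatment in `paired` (with `p_pred_end = pred/n0`).
#' @param members metric names entering the combined GoF.
#' @return object of class `gof_metrics`.
#' @export
gof_metrics <- function(paired, end = NULL,
                        members = c("nrmse", "ppc", "sppe_min", "sppe_max")) {
  if (is.null(end)) {
    sp <- split(as.data.frame(paired), paired$treatment)
    end <- do.call(rbind, lapply(sp, function(d) {
      d <- d[order(d$time), , drop = FALSE]
      last <- d[nrow(d), ]
      # predicted survival probability at the last count: the posterior
      # median probability where available, else the count ratio; floored
      # away from 0/1 so a single stray prediction cannot zero the whole
      # model likelihood
      p <- if (!is.null(last$s_median)) last$s_median else last$pred / last$n0
      data.frame(obs_end = last$obs, pred_end = last$pred, n0 = last$n0,
                 p_pred_end = min(1 - 1e-12, max(1e-12, p)))
    }))
  }
  sp <- sppe(end$obs_end, end$pred_end, end$n0)
  raw <- list(
    nrmse = nrmse(paired),
    ppc = ppc(paired),
    sppe_min = sp$sppe_min,
    sppe_max = sp$sppe_max,
    pseudo_r2 = nagelkerke_r2(end$obs_end, end$n0, end$p_pred_end))
  scaled <- vapply(names(raw), function(nm) scale_metric(nm, raw[[nm]]),
                   numeric(1))
  structure(list(
    raw = raw, sppe_per_treatment = sp$per_treatment, scaled = scaled,
    avg_gof = combine_gof(scaled, "average", members),
    min_gof = combine_gof(scaled, "minimum", members),
    members = members),
    class = "gof_metrics")
}

#' @export
print.gof_metrics <- function(x, ...) {
  cat(sprintf(paste0("<gof_metrics> NRMSE %.1f%%, PPC %.1f%%, SPPE [%.1f%%, %.1f%%], ",
                     "R2 %.3f | avg %.3f, min %.3f\n"),
              x$raw$nrmse, x$raw$ppc, x$raw$sppe_min, x$raw$sppe_max,
              x$raw$pseudo_r2, x$avg_gof, x$min_gof))
  invisible(x)
}
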