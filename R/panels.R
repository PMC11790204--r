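#' Time-series representation of a model fit
#'
#' Builds the panel payloads of a time-series fit image: one panel per
#' treatment showing the observed survival proportions with Wilson
#' intervals, the posterior-median prediction curve, and the 95% credible
#' band (all on the probability scale). Panels carry equal-size metadata so
#' a renderer scales them identically.
#'
#' @param dataset a [survival_dataset()].
#' @param summary a [predict_summary()] aligned to `dataset`.
#' @param image_id,fit_id identifiers stamped on the image.
#' @return object of class `fit_image` with `representation = "TS"`.
#' @export
build_timeseries_panels <- function(dataset, summary, image_id = "img",
                                    fit_id = dataset$id) {
  trs <- all_treatments(dataset)
  tr_ids <- vapply(trs, function(tr) tr$id, character(1))
  assert_that(setequal(tr_ids, unique(summary$treatment)),
              "summary treatments do not match the dataset")
  panels <- lapply(trs, function(tr) {
    s <- summary[summary$treatment == tr$id, , drop = FALSE]
    s <- s[order(s$time), , drop = FALSE]
    wi <- wilson_interval(s$obs, s$n0)
    list(treatment = tr$id,
         time = s$time,
         obs_proportion = s$obs / s$n0,
         wilson_lower = wi$lower,
         wilson_upper = wi$upper,
         pred_median = s$median / s$n0,
         band_lower = s$lower / s$n0,
         band_upper = s$upper / s$n0)
  })
  structure(list(image_id = image_id, fit_id = fit_id, role = dataset$role,
                 representation = "TS", panels = panels,
                 meta = list(equal_panel_size = TRUE)),
            class = "fit_image")
}

#' Dose-response-curve representation of a model fit
#'
#' One panel per experiment: observed end-of-test survival proportions (with
#' Wilson intervals) plotted against each treatment's maximum exposure
#' concentration, and a predicted curve obtained by multiplicatively scaling
#' the experiment's reference exposure profile (the highest-exposure
#' treatment, normalised to unit peak) across a concentration grid and
#' evaluating the posterior end-of-experiment survival (median and 95%
#' band). Because exposure profiles differ in duration and shape between
#' experiments, the predicted curves differ across panels.
#'
#' @param dataset a [survival_dataset()].
#' @param posterior a `guts_posterior`.
#' @param conc_grid multipliers of the experiment's maximum concentration at
#'   which the curve is evaluated (spans the observed maxima by default).
#' @param n_draws posterior draws used for the band.
#' @param image_id,fit_id identifiers.
#' @param seed seed for draw subsampling.
#' @return object of class `fit_image` with `representation = "DRC"`.
#' @export
build_drc_panels <- function(dataset, posterior,
                             conc_grid = exp(seq(log(0.05), log(1.5), length.out = 12)),
                             n_draws = 200L, image_id = "img",
                             fit_id = dataset$id, seed = 1L) {
  assert_that(nrow(posterior$draws) >= 1L, "posterior is empty")
  idx <- with_seed(seed, sample.int(nrow(posterior$draws),
                                    min(n_draws, nrow(posterior$draws))))
  panels <- lapply(seq_along(dataset$experiments), function(ex_i) {
    trs <- dataset$experiments[[ex_i]]
    maxc <- vapply(trs, function(tr) max(tr$profile$concentrations), numeric(1))
    end_obs <- vapply(trs, function(tr) tr$survivors[length(tr$survivors)], numeric(1))
    n0 <- vapply(trs, function(tr) tr$n0, numeric(1))
    t_end <- max(vapply(trs, function(tr) max(tr$obs_times), numeric(1)))
    wi <- wilson_interval(end_obs, n0)
    if (all(maxc == 0)) {
      warning(sprintf("experiment %d has no exposure; flat background-survival curve", ex_i))
      hb_med <- stats::median(posterior$draws[, "hb"])
      flat <- exp(-hb_med * t_end)
      return(list(experiment = ex_i, max_conc = maxc,
                  obs_end_proportion = end_obs / n0,
                  wilson_lower = wi$lower, wilson_upper = wi$upper,
                  curve_conc = conc_grid, curve_median = rep(flat, length(conc_grid)),
                  curve_lower = rep(flat, length(conc_grid)),
                  curve_upper = rep(flat, length(conc_grid)), t_end = t_end))
    }
    ref <- trs[[which.max(maxc)]]$profile
    ref_scale <- max(ref$concentrations)
    abs_grid <- conc_grid * max(maxc)
    Smat <- matrix(0, length(idx), length(abs_grid))
    for (g in seq_along(abs_grid)) {
      prof <- exposure_profile(ref$times, ref$concentrations / ref_scale * abs_grid[g],
                               ref$interpolation)
      for (k in seq_along(idx)) {
        pars <- make_params(posterior$variant, posterior$draws[idx[k], ])
        Smat[k, g] <- predict_survival(prof, pars, t_end)$probabilities
      }
    }
    qs <- apply(Smat, 2, stats::quantile, c(0.025, 0.5, 0.975), names = FALSE)
    list(experiment = ex_i, max_conc = maxc,
         obs_end_proportion = end_obs / n0,
         wilson_lower = wi$lower, wilson_upper = wi$upper,
         curve_conc = abs_grid, curve_median = qs[2, ],
         curve_lower = qs[1, ], curve_upper = qs[3, ], t_end = t_end)
  })
  structure(list(image_id = image_id, fit_id = fit_id, role = dataset$role,
                 representation = "DRC", panels = panels,
                 meta = list(equal_panel_size = TRUE)),
            class = "fit_image")
}

#' @export
print.fit_image <- function(x, ...) {
  cat(sprintf("<fit_image> %s '%s' (%s), %d panel(s)\n",
              x$representation, x$image_id, x$role, length(x$panels)))
  invisible(x)
}

#' Serialize a fit image to JSON
#' @param image a `fit_image`.
#' @param path output path; `NULL` returns the JSON string.
#' @export
write_image_json <- function(image, path = NULL) {
  j <- jsonlite::toJSON(unclass(image), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

#' Compare scores of the two representations of the same fits
#'
#' For every fit evaluated under both representations: the median score per
#' representation (midpoint of the two central values for an even count),
#' the acceptance fraction (scores 1-3 count as acceptance), and a
#' classification by median score into `"DRC better"`, `"equal"` or
#' `"TS better"` (lower median is better). Fits seen under only one
#' representation are skipped with a message.
#'
#' @param records survey-record data frame with columns `fit_id`,
#'   `representation` (`"TS"`/`"DRC"`), `score`.
#' @return list with `per_fit` (data frame) and `counts` (named vector over
#'   the three categories; sums to the number of compared fits).
#' @export
compare_representations <- function(records) {
  assert_that(all(c("fit_id", "representation", "score") %in% names(records)),
              "records need fit_id, representation, score")
  rows <- list()
  skipped <- 0L
  for (fid in unique(records$fit_id)) {
    r <- records[records$fit_id == fid, , drop = FALSE]
    ts <- r$score[r$representation == "TS"]
    drc <- r$score[r$representation == "DRC"]
    if (length(ts) == 0 || length(drc) == 0) { skipped <- skipped + 1L; next }
    med_ts <- stats::median(ts); med_drc <- stats::median(drc)
    cls <- if (med_drc < med_ts) "DRC better"
           else if (med_drc > med_ts) "TS better" else "equal"
    rows[[length(rows) + 1L]] <- data.frame(
      fit_id = fid, median_ts = med_ts, median_drc = med_drc,
      acceptance_ts = mean(ts <= 3), acceptance_drc = mean(drc <= 3),
      n_ts = length(ts), n_drc = length(drc), category = cls)
  }
  if (skipped > 0)
    message(sprintf("%d fit(s) skipped: only one representation evaluated", skipped))
  per_fit <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fit_id = character(), median_ts = numeric(), median_drc = numeric(),
               acceptance_ts = numeric(), acceptance_drc = numeric(),
               n_ts = integer(), n_drc = integer(), category = character())
  counts <- c("DRC better" = sum(per_fit$category == "DRC better"),
              "equal" = sum(per_fit$category == "equal"),
              "TS better" = sum(per_fit$category == "TS better"))
  list(per_fit = per_fit, counts = counts)
}
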