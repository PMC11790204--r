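#' Treatment: one exposure group of a toxicity experiment
#'
#' @param id treatment label.
#' @param profile an [exposure_profile()].
#' @param obs_times strictly increasing observation times starting at 0 (days).
#' @param survivors non-increasing survivor counts at `obs_times`.
#' @param n0 number of tested organisms; defaults to `survivors[1]`.
#' @return object of class `treatment`.
#' @export
treatment <- function(id, profile, obs_times, survivors, n0 = survivors[1]) {
  obs_times <- as.numeric(obs_times)
  survivors <- as.integer(survivors)
  assert_that(inherits(profile, "exposure_profile"), "profile must be an exposure_profile")
  assert_that(length(obs_times) == length(survivors), "obs_times/survivors length mismatch")
  assert_that(obs_times[1] == 0, "observation times must start at 0")
  assert_that(all(diff(obs_times) > 0), "observation times must be strictly increasing")
  assert_that(all(diff(survivors) <= 0), "survivor counts must be non-increasing")
  assert_that(all(survivors >= 0) && all(survivors <= n0),
              "survivors must lie in [0, n0]")
  structure(list(id = as.character(id), profile = profile,
                 obs_times = obs_times, survivors = survivors, n0 = as.integer(n0)),
            class = "treatment")
}

#' Survival dataset: experiments of treatments
#'
#' A dataset groups one or more experiments, each a list of [treatment()]s
#' observed over a shared test duration, in either a calibration or a
#' validation role.
#'
#' @param experiments list of experiments; each experiment is a list of
#'   [treatment()] objects.
#' @param role `"calibration"` or `"validation"`.
#' @param id dataset label.
#' @return object of class `survival_dataset`.
#' @export
survival_dataset <- function(experiments, role = c("calibration", "validation"),
                             id = "dataset") {
  role <- match.arg(role)
  assert_that(length(experiments) >= 1L, "need at least one experiment")
  for (ex in experiments) {
    assert_that(length(ex) >= 1L, "every experiment needs at least one treatment")
    for (tr in ex) assert_that(inherits(tr, "treatment"), "experiments must hold treatment objects")
  }
  structure(list(id = as.character(id), experiments = experiments, role = role),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> '%s' (%s): %d experiment(s), %d treatment(s)\n",
              x$id, x$role, length(x$experiments), length(all_treatments(x))))
  invisible(x)
}

#' Flatten a dataset to its treatments
#' @param dataset a [survival_dataset()].
#' @return list of [treatment()] objects across all experiments.
#' @export
all_treatments <- function(dataset) {
  unlist(dataset$experiments, recursive = FALSE)
}

#' Read a survival dataset from CSV
#'
#' Expects a survival table with columns
#' `dataset,experiment,treatment,time,survivors,n0` and an exposure table
#' with columns `dataset,experiment,treatment,time,concentration` (UTF-8,
#' comma-separated, header row, `.` decimal separator). Row-level validation
#' errors name the offending treatment.
#'
#' @param survival_path path to the survival CSV.
#' @param exposure_path path to the exposure CSV.
#' @param role dataset role.
#' @param interpolation exposure interpolation rule.
#' @return a [survival_dataset()].
#' @export
read_survival_data <- function(survival_path, exposure_path,
                               role = c("calibration", "validation"),
                               interpolation = c("linear", "constant")) {
  role <- match.arg(role)
  interpolation <- match.arg(interpolation)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  expo <- utils::read.csv(exposure_path, stringsAsFactors = FALSE)
  need_s <- c("dataset", "experiment", "treatment", "time", "survivors", "n0")
  need_e <- c("dataset", "experiment", "treatment", "time", "concentration")
  assert_that(all(need_s %in% names(surv)),
              paste("survival CSV must have columns", paste(need_s, collapse = ",")))
  assert_that(all(need_e %in% names(expo)),
              paste("exposure CSV must have columns", paste(need_e, collapse = ",")))
  ds_id <- unique(surv$dataset)
  assert_that(length(ds_id) == 1L, "one dataset per file is expected")
  experiments <- list()
  for (ex_id in unique(surv$experiment)) {
    sx <- surv[surv$experiment == ex_id, , drop = FALSE]
    trts <- list()
    for (tr_id in unique(sx$treatment)) {
      st <- sx[sx$treatment == tr_id, , drop = FALSE]
      st <- st[order(st$time), , drop = FALSE]
      if (any(diff(st$survivors) > 0)) {
        bad <- which(diff(st$survivors) > 0)[1] + 1L
        stop(sprintf("survivor counts increase in dataset %s experiment %s treatment %s at time %g",
                     ds_id, ex_id, tr_id, st$time[bad]), call. = FALSE)
      }
      if (any(st$survivors > st$n0))
        stop(sprintf("survivors exceed n0 in experiment %s treatment %s", ex_id, tr_id),
             call. = FALSE)
      et <- expo[expo$experiment == ex_id & expo$treatment == tr_id, , drop = FALSE]
      if (nrow(et) == 0)
        stop(sprintf("missing exposure profile for experiment %s treatment %s", ex_id, tr_id),
             call. = FALSE)
      et <- et[order(et$time), , drop = FALSE]
      trts[[as.character(tr_id)]] <- treatment(
        id = tr_id,
        profile = exposure_profile(et$time, et$concentration, interpolation),
        obs_times = st$time, survivors = st$survivors, n0 = st$n0[1])
    }
    experiments[[as.character(ex_id)]] <- trts
  }
  survival_dataset(experiments, role = role, id = ds_id)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_data()]; the write/read round trip reproduces
#' the dataset structurally.
#'
#' @param dataset a [survival_dataset()].
#' @inheritParams read_survival_data
#' @return invisibly, the two paths.
#' @export
write_survival_data <- function(dataset, survival_path, exposure_path) {
  srows <- list(); erows <- list()
  for (ex_id in seq_along(dataset$experiments)) {
    ex_name <- names(dataset$experiments)[ex_id] %||% as.character(ex_id)
    if (is.null(names(dataset$experiments)) || ex_name == "") ex_name <- as.character(ex_id)
    for (tr in dataset$experiments[[ex_id]]) {
      srows[[length(srows) + 1L]] <- data.frame(
        dataset = dataset$id, experiment = ex_name, treatment = tr$id,
        time = tr$obs_times, survivors = tr$survivors, n0 = tr$n0)
      erows[[length(erows) + 1L]] <- data.frame(
        dataset = dataset$id, experiment = ex_name, treatment = tr$id,
        time = tr$profile$times, concentration = tr$profile$concentrations)
    }
  }
  utils::write.csv(do.call(rbind, srows), survival_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, erows), exposure_path, row.names = FALSE)
  invisible(c(survival_path, exposure_path))
}
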