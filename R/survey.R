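AFFILIATIONS <- c("academia", "authority", "CRO", "industry", "other", "not specified")

# participant composition of the survey pool (counts out of 64)
DEFAULT_AFFILIATION_COUNTS <- c(academia = 15, authority = 5, CRO = 13,
                                industry = 24, other = 6, "not specified" = 1)
# experience levels coded 5 (modeler with TKTD calibration experience) down
# to 1 (nonmodeler); counts out of 64
DEFAULT_EXPERIENCE_COUNTS <- c("5" = 14, "4" = 16, "3" = 12, "2" = 14, "1" = 8)

#' Generate a synthetic evaluator pool
#'
#' Affiliation and modeling-experience categories are sampled with the
#' composition of the survey population (industry 24/64, academia 15/64,
#' CRO 13/64, ...; experience levels 14/16/12/14/8 from most experienced
#' modeler to nonmodeler).
#'
#' @param n_evaluators pool size (default 64).
#' @param seed integer seed.
#' @param affiliation_counts,experience_counts category weights.
#' @return data frame `evaluator_id`, `affiliation`, `experience` (integer
#'   1-5, 5 = most experienced).
#' @export
generate_evaluators <- function(n_evaluators = 64L, seed = 1L,
                                affiliation_counts = DEFAULT_AFFILIATION_COUNTS,
                                experience_counts = DEFAULT_EXPERIENCE_COUNTS) {
  with_seed(seed, data.frame(
    evaluator_id = sprintf("ev%03d", seq_len(n_evaluators)),
    affiliation = sample(names(affiliation_counts), n_evaluators, replace = TRUE,
                         prob = affiliation_counts / sum(affiliation_counts)),
    experience = as.integer(sample(names(experience_counts), n_evaluators,
                                   replace = TRUE,
                                   prob = experience_counts / sum(experience_counts))),
    stringsAsFactors = FALSE))
}

#' Assign fit images to evaluators
#'
#' Every evaluator sees 20 images in the fixed survey order: five
#' calibrations as time series, five calibrations as dose-response curves,
#' five validations as time series, five validations as dose-response
#' curves. Within each category the images are drawn randomly and
#' independently per evaluator (without replacement within a category).
#' GoF covariates of the assigned fit are attached to each row.
#'
#' @param evaluators an evaluator pool (see [generate_evaluators()]).
#' @param fit_library a fit library (see [simulate_fit_library()]); needs at
#'   least `n_per_category` fits in each role.
#' @param n_per_category images per category (default 5).
#' @param seed integer seed.
#' @return assignment data frame: evaluator columns, `position`, `role`,
#'   `representation`, `fit_id`, `image_id`, and the fit's GoF covariates.
#' @export
generate_survey_design <- function(evaluators, fit_library,
                                   n_per_category = 5L, seed = 1L) {
  gt <- gof_table(fit_library)
  categories <- data.frame(
    role = rep(c("calibration", "validation"), each = 2),
    representation = rep(c("TS", "DRC"), 2))
  for (r in unique(categories$role)) {
    assert_that(sum(gt$role == r) >= n_per_category,
                sprintf("fit library needs >= %d fits with role '%s'",
                        n_per_category, r))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(evaluators)), function(e) {
      per_cat <- lapply(seq_len(nrow(categories)), function(ci) {
        pool <- gt$fit_id[gt$role == categories$role[ci]]
        picks <- sample(pool, n_per_category)
        data.frame(role = categories$role[ci],
                   representation = categories$representation[ci],
                   fit_id = picks, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, per_cat)
      out$position <- seq_len(nrow(out))
      cbind(evaluators[rep(e, nrow(out)), , drop = FALSE], out)
    })
    des <- do.call(rbind, rows)
    rownames(des) <- NULL
    des$image_id <- paste(des$fit_id, des$representation, sep = "_")
    merge(des, gt[, setdiff(names(gt), "role")], by = "fit_id", sort = FALSE)
  })
}

#' Generating ("true") score model for the synthetic survey
#'
#' The latent cumulative ordinal model the synthetic survey draws from:
#' a linear predictor on the combined GoF, image type, affiliation,
#' centred experience, the GoF-by-type and GoF-by-experience interactions,
#' plus a normal evaluator random intercept; 5 increasing cutpoints map the
#' latent scale to scores 1-6. The default geometry has better GoF giving
#' lower (better) scores, experience steepening the GoF slope (more extreme
#' scores for experienced evaluators), and 50% acceptance (score <= 3) close
#' to an average GoF of 0.74 for a reference evaluator. The rejection-reason
#' submodel is a Bernoulli logit on the four scaled metrics whose default
#' coefficients carry the sign pattern "SPPE negative, NRMSE/PPC positive".
#'
#' @param link `"probit"` (latent normal) or `"logit"`.
#' @param cutpoints 5 strictly increasing cutpoints.
#' @param beta_gof slope on the combined GoF (negative = better GoF, better
#'   scores).
#' @param beta_type validation-image offset.
#' @param beta_affiliation named contrasts vs academia.
#' @param beta_experience slope on centred experience (`experience - 3`).
#' @param beta_gof_type,beta_gof_experience interaction coefficients.
#' @param sd_evaluator SD of the evaluator random intercept, `>= 0`.
#' @param reason_coefs intercept + coefficients on scaled
#'   (`sppe_min`, `sppe_max`, `nrmse`, `ppc`) for the end-of-test-reason
#'   logit.
#' @param gof_var which combined metric drives the scores.
#' @return object of class `true_score_model`.
#' @export
true_score_model <- function(link = c("probit", "logit"),
                             cutpoints = -6 * 0.74 + c(-2.0, -0.9, 0, 0.9, 2.0),
                             beta_gof = -6,
                             beta_type = 0.15,
                             beta_affiliation = c(authority = 0.1, CRO = 0.05,
                                                  industry = -0.05, other = 0.1,
                                                  "not specified" = 0),
                             beta_experience = 0.05,
                             beta_gof_type = 0.2,
                             beta_gof_experience = -0.35,
                             sd_evaluator = 0.5,
                             reason_coefs = c(intercept = -0.954,
                                              sppe_min_s = -0.743,
                                              sppe_max_s = -0.654,
                                              nrmse_s = 1.397, ppc_s = 1.028),
                             gof_var = "avg_gof") {
  link <- match.arg(link)
  assert_that(length(cutpoints) == 5 && all(diff(cutpoints) > 0),
              "cutpoints must be 5 strictly increasing values")
  assert_that(sd_evaluator >= 0, "sd_evaluator must be >= 0")
  structure(list(link = link, cutpoints = cutpoints, beta_gof = beta_gof,
                 beta_type = beta_type, beta_affiliation = beta_affiliation,
                 beta_experience = beta_experience,
                 beta_gof_type = beta_gof_type,
                 beta_gof_experience = beta_gof_experience,
                 sd_evaluator = sd_evaluator, reason_coefs = reason_coefs,
                 gof_var = gof_var),
            class = "true_score_model")
}

link_cdf <- function(link) if (link == "probit") stats::pnorm else stats::plogis

score_linear_predictor <- function(truth, assignments) {
  gof <- assignments[[truth$gof_var]]
  is_val <- as.numeric(assignments$role == "validation")
  expc <- assignments$experience - 3
  aff <- truth$beta_affiliation[assignments$affiliation]
  aff[is.na(aff)] <- 0   # academia reference (or unlisted level)
  truth$beta_gof * gof + truth$beta_type * is_val + as.numeric(aff) +
    truth$beta_experience * expc +
    truth$beta_gof_type * gof * is_val +
    truth$beta_gof_experience * gof * expc
}

#' Draw ordinal scores from the generating model
#'
#' Latent `eta = X beta + u(evaluator)`, `u ~ Normal(0, sd)` shared across
#' an evaluator's images; `P(score <= s) = F(cutpoint_s - eta)` with the
#' model's link CDF. Scores are in 1-6 (1 best).
#'
#' @param assignments a design table (see [generate_survey_design()]).
#' @param truth a [true_score_model()].
#' @param seed integer seed.
#' @return `assignments` with columns `score` and `accepted` appended.
#' @export
sample_scores <- function(assignments, truth, seed = 1L) {
  assert_that(inherits(truth, "true_score_model"), "truth must be a true_score_model")
  assert_that(all(diff(truth$cutpoints) > 0), "cutpoints must be increasing")
  assert_that(truth$gof_var %in% names(assignments),
              sprintf("assignments lack covariate '%s'", truth$gof_var))
  F <- link_cdf(truth$link)
  eta_fixed <- score_linear_predictor(truth, assignments)
  with_seed(seed, {
    evs <- unique(assignments$evaluator_id)
    u <- stats::rnorm(length(evs), 0, truth$sd_evaluator)
    names(u) <- evs
    eta <- eta_fixed + u[assignments$evaluator_id]
    cum <- vapply(truth$cutpoints, function(cp) F(cp - eta),
                  numeric(length(eta)))            # n x 5, P(score <= s)
    cum <- matrix(cum, nrow = length(eta))
    un <- stats::runif(length(eta))
    score <- 1L + rowSums(un > cum)                # inversion of the CDF
    assignments$score <- as.integer(score)
    assignments$accepted <- assignments$score <= 3L
    assignments
  })
}

REASONS_TS <- c("a", "b", "c", "d")   # end (multi/one panel), time-course (multi/one)
REASONS_DRC <- c("e", "f", "g", "h")  # shape (multi/one), shifted (multi/one)

#' Attach rejection reasons to non-accepted records
#'
#' Only records with score 4-6 receive a reason. For time-series images the
#' end-of-test vs time-course reason group is drawn from a Bernoulli whose
#' logit is the reason-model linear predictor on the four scaled metrics
#' (response 1 = end-of-test-related); the one- vs multiple-panel letter is
#' drawn from `p_multi`. Dose-response images draw from the DRC reason
#' letters (shape/shifted x multi/one panel) with fixed proportions.
#'
#' @param records scored survey records (see [sample_scores()]).
#' @param truth a [true_score_model()].
#' @param seed integer seed.
#' @param p_multi probability the reason names multiple panels.
#' @param p_drc proportions over the DRC reason letters e-h.
#' @return `records` with a `reasons` column (letter, `""` when accepted).
#' @export
sample_rejection_reasons <- function(records, truth, seed = 1L, p_multi = 0.62,
                                     p_drc = c(e = 0.28, f = 0.12, g = 0.38, h = 0.22)) {
  reasons <- rep("", nrow(records))
  rej <- which(records$score >= 4L)
  if (length(rej)) {
    rc <- truth$reason_coefs
    with_seed(seed, {
      for (i in rej) {
        if (records$representation[i] == "TS") {
          eta <- rc["intercept"] +
            rc["sppe_min_s"] * records$sppe_min_s[i] +
            rc["sppe_max_s"] * records$sppe_max_s[i] +
            rc["nrmse_s"] * records$nrmse_s[i] +
            rc["ppc_s"] * records$ppc_s[i]
          end_related <- stats::runif(1) < stats::plogis(eta)
          multi <- stats::runif(1) < p_multi
          reasons[i] <- if (end_related) (if (multi) "a" else "b")
                        else (if (multi) "c" else "d")
        } else {
          reasons[i] <- sample(names(p_drc), 1, prob = p_drc)
        }
      }
    })
  }
  records$reasons <- reasons
  records
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper: evaluator pool, design, scores and rejection
#' reasons in one call.
#'
#' @param fit_library a fit library.
#' @param truth a [true_score_model()].
#' @param n_evaluators pool size.
#' @param seed integer seed (stage seeds are derived from it).
#' @return survey-record data frame.
#' @export
simulate_survey <- function(fit_library, truth = true_score_model(),
                            n_evaluators = 64L, seed = 1L) {
  ev <- generate_evaluators(n_evaluators, seed = seed)
  des <- generate_survey_design(ev, fit_library, seed = seed + 1L)
  rec <- sample_scores(des, truth, seed = seed + 2L)
  sample_rejection_reasons(rec, truth, seed = seed + 3L)
}

#' Read / write survey records CSV
#'
#' Columns `evaluator_id,affiliation,experience,image_id,fit_id,role,
#' representation,score,reasons` plus any covariate columns; scores are
#' validated to integers 1-6, and reasons may only accompany scores 4-6.
#'
#' @param path CSV path.
#' @return validated records data frame.
#' @export
read_survey_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("evaluator_id", "image_id", "fit_id", "role", "representation",
            "score")
  assert_that(all(need %in% names(rec)),
              paste("survey CSV needs columns", paste(need, collapse = ",")))
  rec$score <- as.integer(rec$score)
  if (any(is.na(rec$score) | rec$score < 1L | rec$score > 6L))
    stop("scores must be integers in 1..6", call. = FALSE)
  if (!is.null(rec$reasons)) {
    rec$reasons[is.na(rec$reasons)] <- ""
    bad <- rec$reasons != "" & rec$score <= 3L
    if (any(bad))
      stop(sprintf("rejection reasons present for accepted records (rows %s)",
                   paste(utils::head(which(bad), 5), collapse = ",")), call. = FALSE)
  }
  rec$accepted <- rec$score <= 3L
  rec
}

#' @rdname read_survey_records
#' @param records a survey-record data frame.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
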