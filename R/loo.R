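# Generalized-Pareto fit to sample tails (Zhang & Stephens 2009 profile
# posterior method), with the weakly-informative shrinkage of the shape
# towards 0.5 that stabilizes small tails.
gpd_fit <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- vapply(seq_len(m), function(j) 1 / sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  sigma <- k / b
  k <- (n * k + 5) / (n + 10)   # shrink shape towards 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance-sampling weights for one observation:
# lw = log raw importance ratios (length S); returns normalized log weights
# and the Pareto-k diagnostic
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- NA_real_
  if (M >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1L):S]
    cutoff <- exp(lw[ord[S - M]])
    exc <- exp(lw[tail_ids]) - cutoff
    if (sum(exc > 0) >= 5) {
      fit <- gpd_fit(exc)
      k <- fit$k
      if (is.finite(k) && is.finite(fit$sigma) && fit$sigma > 0) {
        pp <- (seq_len(M) - 0.5) / M
        smoothed <- log(qgpd(pp, k, fit$sigma) + cutoff)
        lw[tail_ids] <- pmin(smoothed, 0)  # truncate at the raw maximum
      }
    }
  }
  list(log_weights = lw - logsumexp(lw), k = k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Pareto-smoothed importance-sampling estimate of the leave-one-out
#' expected log pointwise predictive density (ELPD-LOO) from the fit's
#' draws-by-observations log-likelihood matrix, with per-observation
#' Pareto-k diagnostics. A warning is attached when more than 10% of
#' observations exceed k = 0.7.
#'
#' @param fit an `ordinal_fit`, or a draws x observations log-likelihood
#'   matrix.
#' @return list: `elpd`, `se`, `pointwise`, `pareto_k`, `n`, `warning`.
#' @export
elpd_loo <- function(fit) {
  ll <- if (is.matrix(fit)) fit else pointwise_loglik(fit)
  n <- ncol(ll)
  pointwise <- numeric(n)
  ks <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_smooth(-ll[, i])
    pointwise[i] <- logsumexp(ps$log_weights + ll[, i])
    ks[i] <- ps$k
  }
  bad <- mean(ks > 0.7, na.rm = TRUE)
  warn <- if (is.finite(bad) && bad > 0.1)
    sprintf("%.0f%% of observations have Pareto k > 0.7; ELPD-LOO may be unreliable",
            100 * bad) else NULL
  if (!is.null(warn)) warning(warn)
  list(elpd = sum(pointwise), se = sqrt(n * stats::var(pointwise)),
       pointwise = pointwise, pareto_k = ks, n = n, warning = warn)
}

# paired standard error of an ELPD difference
elpd_diff_se <- function(pw_a, pw_b) {
  d <- pw_a - pw_b
  sqrt(length(d) * stats::var(d))
}

#' Screen GoF predictors of visual scores by ELPD-LOO
#'
#' Fits one single-predictor cumulative ordinal model per non-empty subset
#' of the five scaled metrics (31 candidates: singletons are the individual
#' metrics; larger subsets are combined by the chosen rule before entering
#' the model), estimates each model's ELPD-LOO by PSIS, and ranks the
#' candidates. Raw ELPD with its SE is reported without multiplicity
#' correction (a comparison, not a test); `se_diff` is the paired SE of the
#' difference to the top candidate.
#'
#' @param records survey records carrying the scaled metric columns
#'   `nrmse_s`, `ppc_s`, `sppe_min_s`, `sppe_max_s`, `pseudo_r2_s`.
#' @param method combination rule for multi-metric candidates.
#' @param link,fit_method,control,seed passed to [fit_cumulative()];
#'   the screen uses fixed-effect-only models (`random_evaluator = FALSE`)
#'   so the pointwise likelihood is exact.
#' @param random_evaluator include the evaluator random intercept.
#' @return object of class `model_comparison`: data frame with `candidate`,
#'   `size`, `elpd`, `se`, `se_diff`, `rank`, `max_pareto_k`, `converged`.
#' @export
rank_predictors <- function(records, method = c("average", "minimum"),
                            link = "probit", fit_method = "laplace",
                            random_evaluator = FALSE,
                            control = ordinal_control(n_iter = 1500L),
                            seed = 1L) {
  method <- match.arg(method)
  metrics <- c("nrmse_s", "ppc_s", "sppe_min_s", "sppe_max_s", "pseudo_r2_s")
  assert_that(all(metrics %in% names(records)),
              "records must carry all five scaled metric columns")
  subsets <- unlist(lapply(1:5, function(k)
    utils::combn(metrics, k, simplify = FALSE)), recursive = FALSE)
  rows <- list()
  pointwise <- list()
  for (ci in seq_along(subsets)) {
    mem <- subsets[[ci]]
    val <- if (length(mem) == 1L) records[[mem]]
           else if (method == "average") rowMeans(records[, mem])
           else do.call(pmin, records[, mem])
    rec <- records
    rec$candidate_gof <- val
    fit <- tryCatch(
      fit_cumulative(rec, gof_var = "candidate_gof", predictors = "gof",
                     random_evaluator = random_evaluator, link = link,
                     method = fit_method, control = control, seed = seed + ci),
      error = function(e) e)
    if (inherits(fit, "error")) {
      message(sprintf("candidate %s failed: %s; excluded from ranking",
                      paste(mem, collapse = "+"), conditionMessage(fit)))
      rows[[ci]] <- data.frame(candidate = paste(mem, collapse = "+"),
                               size = length(mem), elpd = NA, se = NA,
                               max_pareto_k = NA, converged = FALSE)
      pointwise[[ci]] <- NULL
      next
    }
    loo <- suppressWarnings(elpd_loo(fit))
    rows[[ci]] <- data.frame(candidate = paste(mem, collapse = "+"),
                             size = length(mem), elpd = loo$elpd, se = loo$se,
                             max_pareto_k = max(loo$pareto_k, na.rm = TRUE),
                             converged = TRUE)
    pointwise[[ci]] <- loo$pointwise
  }
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$elpd, na.last = "keep", ties.method = "first")
  best <- which(out$rank == 1)
  out$se_diff <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$elpd[i]) || i == best) return(0)
    elpd_diff_se(pointwise[[best]], pointwise[[i]])
  }, numeric(1))
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("model_comparison", "data.frame")
  out
}
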