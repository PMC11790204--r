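# Gauss-Hermite nodes/weights (Golub-Welsch), for integrating the evaluator
# random intercept out of the cumulative-ordinal likelihood
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

ordinal_terms <- function(predictors) {
  known <- c("gof", "type", "affiliation", "experience", "gof:type", "gof:experience")
  bad <- setdiff(predictors, known)
  assert_that(length(bad) == 0,
              paste("unknown predictors:", paste(bad, collapse = ",")))
  predictors
}

# fixed-effect design matrix (no intercept column: the cutpoints absorb it);
# affiliation is dummy-coded against academia, experience is a centred
# integer score (1-5 minus 3)
build_ordinal_design <- function(records, gof_var, predictors) {
  predictors <- ordinal_terms(predictors)
  cols <- list()
  gof <- records[[gof_var]]
  if ("gof" %in% predictors) cols[[gof_var]] <- gof
  if ("type" %in% predictors)
    cols[["type_validation"]] <- as.numeric(records$role == "validation")
  if ("affiliation" %in% predictors) {
    lev <- intersect(AFFILIATIONS, unique(records$affiliation))
    f <- factor(records$affiliation, levels = lev)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0("affil_", lev[-1])
    for (nm in colnames(mm)) cols[[nm]] <- mm[, nm]
  }
  if ("experience" %in% predictors)
    cols[["experience_c"]] <- records$experience - 3
  if ("gof:type" %in% predictors)
    cols[[paste0(gof_var, ":type")]] <- gof * as.numeric(records$role == "validation")
  if ("gof:experience" %in% predictors)
    cols[[paste0(gof_var, ":experience")]] <- gof * (records$experience - 3)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  assert_that(!any(const),
              paste("predictor constant across records:",
                    paste(colnames(X)[const], collapse = ",")))
  X
}

cutpoints_from_unconstrained <- function(zeta) {
  cumsum(c(zeta[1], exp(zeta[-1])))
}

# log-likelihood pieces ------------------------------------------------------

# log category probabilities per observation given cutpoints, eta offset
ordinal_logprob <- function(score, cuts, eta, F) {
  upper <- c(cuts, Inf)[score]
  lower <- c(-Inf, cuts)[score]
  log(pmax(F(upper - eta) - F(lower - eta), 1e-300))
}

#' Sampler settings for the cumulative ordinal model
#' @param n_chains,n_iter,thin MCMC settings (50% burn-in is discarded).
#' @param n_nodes Gauss-Hermite nodes for the random-intercept integral.
#' @param n_draws_laplace draws taken from the Laplace approximation.
#' @return settings list.
#' @export
ordinal_control <- function(n_chains = 4L, n_iter = 3000L, thin = 2L,
                            n_nodes = 15L, n_draws_laplace = 1000L) {
  list(n_chains = n_chains, n_iter = n_iter, thin = thin,
       n_nodes = n_nodes, n_draws_laplace = n_draws_laplace)
}

#' Bayesian cumulative ordinal regression of visual scores
#'
#' Models the 1-6 score as an ordered categorical outcome with a latent
#' continuous variable (normal under the default probit link, logistic under
#' logit) cut at 5 increasing thresholds. Fixed effects are chosen from the
#' vocabulary `gof`, `type` (calibration/validation), `affiliation` (dummy
#' coded against academia), `experience` (centred 1-5 score), `gof:type`,
#' `gof:experience`; an evaluator random intercept is integrated out of the
#' likelihood by Gauss-Hermite quadrature. Priors: Normal(0, 2.5) on
#' coefficients, Normal(0, 5) on cutpoints (ordered transform), half-Normal(0, 2)
#' on the random-intercept SD. Estimation is either adaptive-Metropolis MCMC
#' (`method = "mcmc"`) or a Laplace approximation around the penalized-likelihood
#' mode (`method = "laplace"`, used where speed matters; the two agree on
#' well-behaved data).
#'
#' @param records survey records (need `score`, the `gof_var` column, and the
#'   covariates used by `predictors`).
#' @param gof_var name of the continuous GoF column driving `gof` terms.
#' @param predictors character vector of fixed-effect terms.
#' @param random_evaluator include the evaluator random intercept.
#' @param link `"probit"` or `"logit"`.
#' @param method `"mcmc"` or `"laplace"`.
#' @param control an [ordinal_control()].
#' @param seed integer seed.
#' @return object of class `ordinal_fit`: `draws` (natural scale: `cut1..cut5`,
#'   coefficients, `sigma_evaluator`), `diagnostics`, design info.
#' @export
fit_cumulative <- function(records, gof_var = "avg_gof",
                           predictors = c("gof", "type", "affiliation",
                                          "experience", "gof:type",
                                          "gof:experience"),
                           random_evaluator = TRUE,
                           link = c("probit", "logit"),
                           method = c("mcmc", "laplace"),
                           control = ordinal_control(), seed = 1L) {
  link <- match.arg(link)
  method <- match.arg(method)
  score <- as.integer(records$score)
  assert_that(length(unique(score)) >= 2, "need at least 2 distinct scores")
  assert_that(all(score >= 1 & score <= 6), "scores must lie in 1..6")
  X <- build_ordinal_design(records, gof_var, predictors)
  p <- ncol(X)
  F <- link_cdf(link)
  if (random_evaluator) {
    group <- as.integer(factor(records$evaluator_id))
    gh <- gauss_hermite(control$n_nodes)
    log_w <- log(gh$weights / sqrt(pi))
  }
  d <- 5L + p + as.integer(random_evaluator)

  log_post <- function(theta) {
    zeta <- theta[1:5]
    beta <- theta[5 + seq_len(p)]
    cuts <- cutpoints_from_unconstrained(zeta)
    eta <- as.numeric(X %*% beta)
    lp <- sum(stats::dnorm(cuts, 0, 5, log = TRUE)) + sum(zeta[-1]) +
      sum(stats::dnorm(beta, 0, 2.5, log = TRUE))
    if (!random_evaluator) {
      ll <- sum(ordinal_logprob(score, cuts, eta, F))
      return(ll + lp)
    }
    log_sigma <- theta[d]
    sigma <- exp(log_sigma)
    lp <- lp + stats::dnorm(sigma, 0, 2, log = TRUE) + log(2) + log_sigma
    u <- sqrt(2) * sigma * gh$nodes
    lpmat <- vapply(u, function(uk) ordinal_logprob(score, cuts, eta + uk, F),
                    numeric(length(score)))
    gsum <- rowsum(lpmat, group)                  # evaluators x nodes
    ll <- sum(row_logsumexp(sweep(gsum, 2, log_w, `+`)))
    ll + lp
  }

  # initial values: cutpoints from marginal score frequencies, slopes at zero
  freq <- cumsum(tabulate(score, 6))[1:5] / length(score)
  freq <- pmin(pmax(freq, 0.02), 0.98)
  Finv <- if (link == "probit") stats::qnorm else stats::qlogis
  c0 <- Finv(freq)
  c0 <- cummax(c0 + seq(0, 1e-3, length.out = 5))
  init <- c(c0[1], log(pmax(diff(c0), 0.05)), rep(0, p),
            if (random_evaluator) log(0.5))

  # penalized-likelihood mode and curvature: the Laplace approximation
  # itself in "laplace" mode, and the chain initialization / proposal shape
  # in "mcmc" mode
  opt <- stats::optim(init, function(th) -log_post(th), method = "BFGS",
                      hessian = TRUE, control = list(maxit = 1000))
  Sig <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(Sig) || !all(is.finite(Sig))) Sig <- diag(1e-4, d)
  ev <- eigen(Sig, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  Sig <- ev$vectors %*% diag(ev$values, d) %*% t(ev$vectors)
  L <- t(chol(Sig))

  if (method == "mcmc") {
    res <- run_metropolis(log_post, opt$par, n_chains = control$n_chains,
                          n_iter = control$n_iter, thin = control$thin,
                          seed = seed, init_jitter = 1, init_cov_chol = L)
    raw <- res$draws
    diagnostics <- list(rhat = split_rhat(res$chains), ess = ess_basic(res$chains),
                        accept = res$accept, mode = opt$par)
  } else {
    raw <- with_seed(seed, {
      zmat <- matrix(stats::rnorm(control$n_draws_laplace * d), ncol = d)
      t(opt$par + L %*% t(zmat))
    })
    diagnostics <- list(convergence = opt$convergence, mode = opt$par,
                        neg_logpost = opt$value)
  }

  draws <- matrix(0, nrow(raw), 5L + p + 1L)
  for (s in seq_len(nrow(raw)))
    draws[s, 1:5] <- cutpoints_from_unconstrained(raw[s, 1:5])
  draws[, 5 + seq_len(p)] <- raw[, 5 + seq_len(p), drop = FALSE]
  draws[, 5 + p + 1] <- if (random_evaluator) exp(raw[, d]) else 0
  colnames(draws) <- c(paste0("cut", 1:5), colnames(X), "sigma_evaluator")
  structure(list(
    link = link, method = method, draws = draws, diagnostics = diagnostics,
    X = X, score = score,
    group = if (random_evaluator) as.integer(factor(records$evaluator_id)) else NULL,
    random_evaluator = random_evaluator, gof_var = gof_var,
    predictors = predictors, n = length(score), seed = seed,
    control = control),
    class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> link=%s method=%s n=%d draws=%d%s\n",
              x$link, x$method, x$n, nrow(x$draws),
              if (x$random_evaluator) " +evaluator RE" else ""))
  print(coef_table(x))
  invisible(x)
}

#' Posterior coefficient summary
#' @param fit an `ordinal_fit`.
#' @return data frame of median, mean, sd and 95% credible bounds.
#' @export
coef_table <- function(fit) {
  qs <- t(apply(fit$draws, 2, stats::quantile, c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(parameter = colnames(fit$draws),
             median = qs[, 1], mean = colMeans(fit$draws),
             sd = apply(fit$draws, 2, stats::sd),
             lower95 = qs[, 2], upper95 = qs[, 3], row.names = NULL)
}

#' Per-observation category probabilities at the posterior median
#' @param fit an `ordinal_fit`.
#' @return matrix n x 6 of probabilities (rows sum to 1); for random-effect
#'   fits these are marginal over the evaluator intercept.
#' @export
category_probs <- function(fit) {
  med <- apply(fit$draws, 2, stats::median)
  cuts <- med[1:5]
  beta <- med[5 + seq_len(ncol(fit$X))]
  eta <- as.numeric(fit$X %*% beta)
  F <- link_cdf(fit$link)
  out <- matrix(0, fit$n, 6)
  if (fit$random_evaluator && med["sigma_evaluator"] > 0) {
    gh <- gauss_hermite(fit$control$n_nodes)
    w <- gh$weights / sqrt(pi)
    u <- sqrt(2) * med["sigma_evaluator"] * gh$nodes
    for (s in 1:6) {
      upper <- c(cuts, Inf)[s]; lower <- c(-Inf, cuts)[s]
      acc <- 0
      for (k in seq_along(u))
        acc <- acc + w[k] * (F(upper - eta - u[k]) - F(lower - eta - u[k]))
      out[, s] <- acc
    }
  } else {
    for (s in 1:6) {
      upper <- c(cuts, Inf)[s]; lower <- c(-Inf, cuts)[s]
      out[, s] <- F(upper - eta) - F(lower - eta)
    }
  }
  out
}

# draws x n pointwise log-likelihood matrix; for random-effect fits the
# per-observation marginal (intercept integrated against its prior) is used
pointwise_loglik <- function(fit) {
  S <- nrow(fit$draws)
  n <- fit$n
  F <- link_cdf(fit$link)
  p <- ncol(fit$X)
  out <- matrix(0, S, n)
  if (fit$random_evaluator) {
    gh <- gauss_hermite(fit$control$n_nodes)
    log_w <- log(gh$weights / sqrt(pi))
  }
  for (s in seq_len(S)) {
    cuts <- fit$draws[s, 1:5]
    beta <- fit$draws[s, 5 + seq_len(p)]
    eta <- as.numeric(fit$X %*% beta)
    if (fit$random_evaluator) {
      sigma <- fit$draws[s, "sigma_evaluator"]
      u <- sqrt(2) * sigma * gh$nodes
      lpmat <- vapply(u, function(uk)
        ordinal_logprob(fit$score, cuts, eta + uk, F), numeric(n))
      out[s, ] <- row_logsumexp(sweep(lpmat, 2, log_w, `+`))
    } else {
      out[s, ] <- ordinal_logprob(fit$score, cuts, eta, F)
    }
  }
  out
}
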