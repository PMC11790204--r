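# Adaptive random-walk Metropolis engine shared by the GUTS calibration and
# the ordinal-regression samplers. Proposals are multivariate normal with a
# covariance adapted during burn-in (empirical covariance of the chain
# history, scaled towards a target acceptance rate) and frozen afterwards,
# so the retained draws form a valid Markov chain.

run_metropolis <- function(log_post, init, n_chains = 4L, n_iter = 2000L,
                           burn_frac = 0.5, thin = 1L, seed = 1L,
                           init_jitter = 0.2, target_accept = 0.3,
                           init_cov_chol = NULL) {
  d <- length(init)
  n_burn <- floor(n_iter * burn_frac)
  with_seed(seed, {
    chains <- vector("list", n_chains)
    lps <- vector("list", n_chains)
    acc_rates <- numeric(n_chains)
    for (ch in seq_len(n_chains)) {
      jitter_one <- function() {
        if (is.null(init_cov_chol)) init + stats::rnorm(d, 0, init_jitter)
        else init + init_jitter * as.numeric(init_cov_chol %*% stats::rnorm(d))
      }
      x <- jitter_one()
      lp <- log_post(x)
      tries <- 0
      while (!is.finite(lp) && tries < 200) {
        x <- jitter_one()
        lp <- log_post(x)
        tries <- tries + 1
      }
      if (!is.finite(lp)) stop("could not find a finite starting point", call. = FALSE)
      log_scale <- log(2.38^2 / d)
      cov_chol <- init_cov_chol %||% diag(d)
      hist_mat <- matrix(0, n_iter, d)
      lp_vec <- numeric(n_iter)
      n_acc <- 0
      for (it in seq_len(n_iter)) {
        prop <- x + exp(log_scale / 2) * as.numeric(cov_chol %*% stats::rnorm(d))
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          x <- prop; lp <- lp_prop; n_acc <- n_acc + 1
          acc <- 1
        } else acc <- 0
        hist_mat[it, ] <- x
        lp_vec[it] <- lp
        if (it <= n_burn) {
          # Robbins-Monro scale adaptation + periodic covariance refresh
          log_scale <- log_scale + (acc - target_accept) / sqrt(it)
          if (it >= 50 && it %% 50 == 0) {
            cv <- stats::cov(hist_mat[max(1, it - 500):it, , drop = FALSE])
            cv <- cv + diag(1e-8, d)
            ch_try <- tryCatch(chol(cv), error = function(e) NULL)
            if (!is.null(ch_try)) cov_chol <- t(ch_try)
          }
        }
      }
      keep <- seq(n_burn + 1L, n_iter, by = thin)
      chains[[ch]] <- hist_mat[keep, , drop = FALSE]
      lps[[ch]] <- lp_vec[keep]
      acc_rates[ch] <- n_acc / n_iter
    }
    list(chains = chains, lp = lps, accept = acc_rates,
         draws = do.call(rbind, chains), lp_all = unlist(lps))
  })
}

# split-Rhat (Gelman et al.): each chain halved, between/within variance ratio
split_rhat <- function(chains) {
  d <- ncol(chains[[1]])
  halves <- list()
  for (chn in chains) {
    n <- nrow(chn)
    h <- floor(n / 2)
    halves[[length(halves) + 1L]] <- chn[seq_len(h), , drop = FALSE]
    halves[[length(halves) + 1L]] <- chn[seq(h + 1L, 2L * h), , drop = FALSE]
  }
  vapply(seq_len(d), function(j) {
    m <- length(halves)
    n <- nrow(halves[[1]])
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# effective sample size via Geyer's initial positive sequence, per parameter,
# pooled across chains
ess_basic <- function(chains) {
  d <- ncol(chains[[1]])
  vapply(seq_len(d), function(j) {
    total <- 0
    for (chn in chains) {
      x <- chn[, j]
      n <- length(x)
      v <- stats::var(x)
      if (v <= 0) { total <- total + n; next }
      ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                       demean = TRUE)$acf[, 1, 1]
      s <- 1
      k <- 2
      while (k + 1 <= length(ac)) {
        pair <- ac[k] + ac[k + 1]
        if (pair < 0) break
        s <- s + 2 * pair
        k <- k + 2
      }
      total <- total + n / max(s, 1)
    }
    total
  }, numeric(1))
}
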