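make_two_point_dataset <- function(survivors, n0 = 10L, conc = 1) {
  survival_dataset(list(list(
    treatment("t1", exposure_profile(0, conc), c(0, 1), survivors, n0))))
}

test_that("conditional-binomial likelihood matches direct binomial pmf", {
  # predicted S = [1, 0.8] arises from hb with exp(-hb) = 0.8 and b = 0
  hb <- -log(0.8)
  ds <- make_two_point_dataset(c(10L, 8L))
  par <- guts_params_sd(hb = hb, kd = 1, z = 10, b = 0)
  expect_equal(log_likelihood(ds, par), dbinom(8, 10, 0.8, log = TRUE),
               tolerance = 1e-12)
  expect_equal(log_likelihood(ds, par), log(45 * 0.8^8 * 0.2^2),
               tolerance = 1e-9)
  # no deaths predicted certain: log-likelihood 0
  ds1 <- make_two_point_dataset(c(10L, 10L))
  expect_equal(log_likelihood(ds1, guts_params_sd(0, 1, 10, 0)), 0)
})

test_that("conditional-binomial sum equals the multinomial death likelihood", {
  for (s in 1:20) {
    set.seed(s)
    par <- guts_params_sd(hb = 0.05, kd = runif(1, 0.3, 2), z = runif(1, 0.3, 1),
                          b = runif(1, 0.2, 1))
    prof <- exposure_profile(0, runif(1, 0.5, 3))
    obs_times <- 0:4
    n0 <- 12L
    S <- survival_sd(prof, par, obs_times)$probabilities
    counts <- sort(sample(0:n0, length(obs_times), replace = TRUE),
                   decreasing = TRUE)
    counts[1] <- n0
    ds <- survival_dataset(list(list(
      treatment("t", prof, obs_times, counts, n0))))
    # multinomial over interval deaths + final survivors
    deaths <- -diff(counts)
    p_int <- -diff(S)
    probs <- c(p_int, S[length(S)])
    ll_multi <- lgamma(n0 + 1) - sum(lgamma(c(deaths, counts[length(counts)]) + 1)) +
      sum(c(deaths, counts[length(counts)]) * log(probs))
    expect_equal(log_likelihood(ds, par), ll_multi, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to treatment order", {
  set.seed(11)
  par <- guts_params_sd(0.02, 0.8, 1, 0.3)
  trts <- lapply(1:3, function(i) {
    prof <- exposure_profile(0, i)
    curve <- survival_sd(prof, par, 0:4)
    treatment(sprintf("t%d", i), prof, 0:4,
              sample_survival_counts(curve, 20, seed = i), 20)
  })
  d1 <- survival_dataset(list(trts))
  d2 <- survival_dataset(list(rev(trts)))
  expect_equal(log_likelihood(d1, par), log_likelihood(d2, par))
})

test_that("zero predicted survival with observed survivors yields -Inf", {
  ds <- make_two_point_dataset(c(10L, 5L), conc = 100)
  par <- guts_params_sd(hb = 0, kd = 1e3, z = 0.01, b = 100)
  expect_identical(log_likelihood(ds, par), -Inf)
})

test_that("posterior sampling is seed-deterministic and flags diagnostics", {
  ds <- simulate_recovery_dataset(n0 = 20L, seed = 5)
  ctrl <- calibration_control(n_iter = 400L, thin = 1L)
  p1 <- fit_posterior(ds, "SD", control = ctrl, seed = 3)
  p2 <- fit_posterior(ds, "SD", control = ctrl, seed = 3)
  expect_identical(p1$draws, p2$draws)
  expect_named(p1$diagnostics$rhat, c("hb", "kd", "z", "b"))
  expect_true(all(is.finite(p1$log_lik)))
  expect_equal(nrow(p1$draws), ctrl$n_chains * ctrl$n_iter / 2)
})

test_that("all-control datasets are rejected as unidentifiable", {
  par <- guts_params_sd(0.02, 1, 1, 0.5)
  ds <- simulate_survival_dataset(par, concentrations = c(0, 0, 0), n0 = 10,
                                  obs_times = 0:3, seed = 1)
  expect_error(fit_posterior(ds, "SD"), "unidentifiable")
})

test_that("IT calibration runs and recovers the threshold scale", {
  true <- guts_params_it(hb = 0.02, kd = 1.2, mw = 1, beta = 3)
  ds <- simulate_survival_dataset(true, concentrations = c(0, 0.5, 1, 2, 4),
                                  n0 = 50, obs_times = c(0, 1, 2, 4, 7),
                                  seed = 21)
  post <- fit_posterior(ds, "IT", control = calibration_control(n_iter = 1200L),
                        seed = 2)
  med <- apply(post$draws, 2, median)
  q <- apply(post$draws, 2, quantile, c(0.025, 0.975))
  expect_true(q[1, "mw"] <= 1 && 1 <= q[2, "mw"])
  expect_lt(abs(med["mw"] - 1), 0.5)
})

test_that("prediction summaries respect bounds and degenerate posteriors", {
  ds <- simulate_recovery_dataset(n0 = 20L, seed = 8)
  post <- fit_posterior(ds, "SD", control = calibration_control(n_iter = 400L),
                        seed = 4)
  summ <- predict_summary(ds, post, n_draws = 200, seed = 1)
  expect_true(all(summ$lower <= summ$median & summ$median <= summ$upper))
  expect_true(all(summ$lower >= 0 & summ$upper <= summ$n0))
  # single-draw posterior without sampling error: zero-width intervals
  one <- post
  one$draws <- post$draws[1, , drop = FALSE]
  s1 <- predict_summary(ds, one, include_sampling_error = FALSE, n_draws = 1,
                        seed = 1)
  expect_equal(s1$lower, s1$upper)
  expect_equal(s1$median, s1$n0 * s1$s_median, tolerance = 1e-9)
  # requesting more draws than available warns and resamples
  expect_warning(predict_summary(ds, one, n_draws = 5, seed = 1),
                 "replacement")
})

test_that("posterior predictive intervals cover fresh observations", {
  true <- guts_params_sd(0.02, 0.8, 1, 0.3)
  ds <- simulate_recovery_dataset(true, n0 = 50L, seed = 31)
  # posterior concentrated at the truth isolates the sampling-error layer
  post <- structure(list(
    variant = "SD",
    draws = matrix(rep(c(0.02, 0.8, 1, 0.3), each = 400), 400,
                   dimnames = list(NULL, c("hb", "kd", "z", "b")))),
    class = "guts_posterior")
  summ <- predict_summary(ds, post, include_sampling_error = TRUE,
                          n_draws = 400, seed = 3)
  hits <- 0L; total <- 0L
  for (rep in 1:60) {
    fresh <- simulate_recovery_dataset(true, n0 = 50L, seed = 4000 + rep)
    obs <- do.call(rbind, lapply(all_treatments(fresh), function(tr)
      data.frame(treatment = tr$id, time = tr$obs_times, obs = tr$survivors)))
    m <- merge(obs, as.data.frame(summ)[, c("treatment", "time", "lower", "upper")])
    m <- m[m$time > 0, ]
    hits <- hits + sum(m$obs >= m$lower & m$obs <= m$upper)
    total <- total + nrow(m)
  }
  expect_gt(hits / total, 0.92)
  expect_lt(hits / total, 0.995)
})

test_that("posterior interquartile range shrinks with more organisms", {
  iqr_for <- function(n0, seed) {
    ds <- simulate_recovery_dataset(n0 = n0, seed = seed)
    post <- fit_posterior(ds, "SD", control = calibration_control(n_iter = 1000L),
                          seed = seed)
    apply(log(post$draws[, c("kd", "z", "b")]), 2, IQR)
  }
  wins <- 0L
  for (s in 1:3) {
    small <- iqr_for(25L, 60 + s)
    big <- iqr_for(100L, 60 + s)
    wins <- wins + sum(big < small)
  }
  expect_gte(wins, 7)   # 9 comparisons; concentration must dominate
})
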