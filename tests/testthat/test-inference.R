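fast_ctrl <- ordinal_control(n_iter = 1500L, thin = 2L)

test_that("cumulative-model category probabilities are normalized", {
  rec <- make_screen_records(1, n_ev = 12L)
  rec$avg_gof <- rowMeans(rec[, c("nrmse_s", "ppc_s", "sppe_min_s")])
  fit <- fit_cumulative(rec, predictors = "gof",
                        random_evaluator = FALSE, method = "laplace", seed = 2)
  probs <- category_probs(fit)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-12)
  expect_true(all(probs >= 0))
})

test_that("cumulative model rejects degenerate inputs", {
  rec <- make_screen_records(2, n_ev = 8L)
  rec$avg_gof <- 0.5
  expect_error(fit_cumulative(rec, gof_var = "avg_gof", predictors = "gof"),
               "constant")
  rec2 <- make_screen_records(2, n_ev = 8L)
  rec2$score <- 2L
  rec2$avg_gof <- rec2$nrmse_s
  expect_error(fit_cumulative(rec2, predictors = "gof"), "distinct scores")
})

test_that("a null GoF effect is not detected as signal", {
  hits <- 0L
  for (r in 1:6) {
    rec <- make_screen_records(100 + r, n_ev = 15L, beta = -4)
    rec$noise_gof <- runif(nrow(rec))    # unrelated to the scores
    fit <- fit_cumulative(rec, gof_var = "noise_gof", predictors = "gof",
                          random_evaluator = FALSE, method = "laplace",
                          seed = r)
    ct <- coef_table(fit)
    row <- ct[ct$parameter == "noise_gof", ]
    hits <- hits + (row$lower95 <= 0 && 0 <= row$upper95)
  }
  expect_gte(hits, 5L)
})

test_that("a strong negative GoF effect is recovered with the right sign", {
  rec <- make_screen_records(7, n_ev = 25L, members = "nrmse_s", beta = -6)
  rec$avg_gof <- rec$nrmse_s
  fit <- fit_cumulative(rec, predictors = "gof", random_evaluator = FALSE,
                        method = "mcmc", control = fast_ctrl, seed = 3)
  expect_gt(mean(fit$draws[, "avg_gof"] < 0), 0.99)
  ct <- coef_table(fit)
  row <- ct[ct$parameter == "avg_gof", ]
  expect_true(row$lower95 <= -6 && -6 <= row$upper95)
})

test_that("MCMC and Laplace modes agree on the full random-effect model", {
  lib <- simulate_fit_library(16L, seed = 5)
  rec <- simulate_survey(lib, n_evaluators = 30L, seed = 13)
  fl <- fit_cumulative(rec, method = "laplace", seed = 4)
  fm <- fit_cumulative(rec, method = "mcmc",
                       control = ordinal_control(n_iter = 2000L), seed = 4)
  cl <- coef_table(fl); cm <- coef_table(fm)
  for (par in c("avg_gof", "sigma_evaluator")) {
    a <- cl[cl$parameter == par, ]; b <- cm[cm$parameter == par, ]
    expect_lt(abs(a$median - b$median), 3 * max(a$sd, b$sd))
  }
})

test_that("ELPD-LOO is insensitive to a pure-noise predictor", {
  wins <- 0L
  for (r in 1:5) {
    rec <- make_screen_records(300 + r, n_ev = 15L, members = "nrmse_s",
                               beta = -5)
    rec$avg_gof <- rec$nrmse_s
    rec$noise <- runif(nrow(rec))
    f1 <- fit_cumulative(rec, predictors = "gof", random_evaluator = FALSE,
                         method = "laplace", seed = r)
    # same model plus the noise column entering through the experience slot
    rec$experience <- rec$noise
    f2 <- fit_cumulative(rec, predictors = c("gof", "experience"),
                         random_evaluator = FALSE, method = "laplace", seed = r)
    l1 <- suppressWarnings(elpd_loo(f1))
    l2 <- suppressWarnings(elpd_loo(f2))
    wins <- wins + (l2$elpd - l1$elpd <= elpd_diff_se(l2$pointwise, l1$pointwise) + 1e-9)
  }
  expect_gte(wins, 4L)
})

test_that("well-specified fits have small Pareto-k diagnostics", {
  rec <- make_screen_records(9, n_ev = 15L, members = "ppc_s", beta = -5)
  rec$avg_gof <- rec$ppc_s
  fit <- fit_cumulative(rec, predictors = "gof", random_evaluator = FALSE,
                        method = "laplace", seed = 5)
  loo <- elpd_loo(fit)
  expect_true(all(loo$pareto_k < 0.7, na.rm = TRUE))
  expect_true(is.finite(loo$elpd) && is.finite(loo$se))
})

test_that("the predictor screen enumerates all 31 candidate subsets", {
  rec <- make_screen_records(11, n_ev = 10L, per_ev = 10L)
  cmp <- rank_predictors(rec, "average", seed = 2)
  expect_equal(nrow(cmp), 31L)
  expect_equal(sort(cmp$rank), 1:31)
  expect_equal(sum(cmp$size == 1), 5L)
  expect_equal(cmp$se_diff[cmp$rank == 1], 0)
  # ranks are consistent with the elpd ordering
  expect_true(all(diff(cmp$elpd[order(cmp$rank)]) <= 1e-9))
})

test_that("acceptance logit recovers known coefficients", {
  set.seed(21)
  n <- 1000L
  gof <- runif(n, 0.3, 1)
  p <- plogis(-7.4 + 10 * gof)
  rec <- data.frame(score = ifelse(runif(n) < p, 2L, 5L), avg_gof = gof)
  fit <- fit_acceptance_logit(rec, "avg_gof")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef["a"] + 7.4), 2 * se[1])
  expect_lt(abs(fit$coef["b"] - 10), 2 * se[2])
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("a metric unrelated to acceptance has a null slope", {
  set.seed(22)
  n <- 600L
  rec <- data.frame(score = sample(c(2L, 5L), n, replace = TRUE),
                    avg_gof = runif(n))
  fit <- fit_acceptance_logit(rec, "avg_gof")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef["b"]), 3 * se[2])
})

test_that("the 50% threshold is the analytic root of the logit", {
  fake <- structure(list(predictor = "avg_gof", coef = c(a = -3, b = 5),
                         vcov = diag(1e-6, 2),
                         sims = cbind(a = rnorm(100, -3, 1e-4),
                                      b = rnorm(100, 5, 1e-4)),
                         n = 100L),
                    class = "logit_fit")
  th <- acceptance_threshold(fake)
  expect_equal(th$threshold, 0.6, tolerance = 1e-10)
  # invariant to common rescaling of (a, b)
  fake2 <- fake
  fake2$coef <- fake$coef * 7.3
  fake2$sims <- fake$sims * 7.3
  expect_equal(acceptance_threshold(fake2)$threshold, th$threshold,
               tolerance = 1e-10)
  # negative slope is flagged, not silent
  fake3 <- fake
  fake3$coef <- c(a = 3, b = -5)
  expect_warning(th3 <- acceptance_threshold(fake3), "slope")
  expect_false(is.null(th3$flag))
})

test_that("rejection-reason model uses only grouped rejected records", {
  set.seed(31)
  n <- 600L
  rec <- data.frame(score = rep(c(2L, 5L), each = n / 2),
                    representation = "TS",
                    reasons = rep(c("", "a"), each = n / 2),
                    sppe_min_s = runif(n), sppe_max_s = runif(n),
                    nrmse_s = runif(n), ppc_s = runif(n))
  rec$reasons[rec$score == 5L] <- sample(c("a", "b", "c", "d"), n / 2,
                                         replace = TRUE)
  out <- fit_rejection_reason_model(rec)
  expect_equal(attr(out, "n"), n / 2)        # accepted records excluded
  expect_equal(out$term, c("intercept", "sppe_min", "sppe_max", "nrmse", "ppc"))
  rec_const <- rec
  rec_const$nrmse_s <- 0.5
  expect_error(fit_rejection_reason_model(rec_const), "constant")
  rec_one <- rec
  rec_one$reasons[rec_one$score == 5L] <- "a"
  expect_error(fit_rejection_reason_model(rec_one), "both reason groups")
})

test_that("representation acceptance model recovers a built-in difference", {
  set.seed(41)
  n <- 800L
  rep_type <- rep(c("TS", "DRC"), each = n / 2)
  p <- ifelse(rep_type == "DRC", 0.75, 0.55)
  rec <- data.frame(representation = rep_type,
                    score = ifelse(runif(n) < p, 2L, 5L))
  fit <- fit_representation_acceptance(rec, seed = 1)
  se <- sqrt(diag(fit$vcov))
  expect_gt(fit$coef["b"], 0)
  expect_gt(fit$coef["b"] / se[2], 2)
  # equal rates by construction: interval contains zero
  rec0 <- data.frame(representation = rep_type,
                     score = rep(rep(c(2L, 5L), each = n / 4), 2))
  fit0 <- fit_representation_acceptance(rec0, seed = 1)
  se0 <- sqrt(diag(fit0$vcov))
  expect_lt(abs(fit0$coef["b"]), 2.5 * se0[2])
  expect_error(fit_representation_acceptance(rec[rec$representation == "TS", ]),
               "both representations")
})
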