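test_that("exposure profiles validate their invariants", {
  expect_error(exposure_profile(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(exposure_profile(c(0, 1), c(-1, 0)), "non-negative")
  expect_error(exposure_profile(numeric(), numeric()), "at least one")
  p <- exposure_profile(c(0, 2), c(1, 3))
  expect_equal(conc_at(p, 1), 2)                    # linear interpolation
  expect_equal(conc_at(p, 5), 3)                    # held beyond support
  pc <- exposure_profile(c(0, 2), c(1, 3), "constant")
  expect_equal(conc_at(pc, 1), 1)
})

test_that("damage matches piecewise closed forms", {
  # constant exposure: D = C (1 - exp(-kd t))
  expect_equal(damage_series(exposure_profile(0, 2), 0.5, 2),
               2 * (1 - exp(-1)), tolerance = 1e-12)
  # zero exposure gives zero damage
  expect_equal(damage_series(exposure_profile(0, 0), 1.3, c(1, 5)), c(0, 0))
  # square pulse then depuration
  pulse <- exposure_profile(c(0, 1, 1 + 1e-9, 3), c(1, 1, 0, 0))
  D <- damage_series(pulse, 1, c(1, 2))
  expect_equal(D[1], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(D[2], (1 - exp(-1)) * exp(-1), tolerance = 1e-6)
  # fast-kinetics limit D -> C
  expect_equal(damage_series(exposure_profile(0, 3), 1e3, 1), 3, tolerance = 1e-3)
  expect_error(damage_series(exposure_profile(0, 1), -1, 1), "positive")
  expect_error(damage_series(exposure_profile(0, 1), 1, c(2, 1)), "increasing")
})

test_that("piecewise-analytic damage agrees with adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  for (s in 1:20) {
    prof <- random_profile(900 + s)
    kd <- runif(1, 0.05, 5)
    times <- sort(runif(4, 0.1, max(prof$times) + 1.5))
    ana <- damage_series(prof, kd, times)
    num <- numeric_damage(prof, kd, times)
    expect_equal(ana, num, tolerance = 1e-8)
  }
})

test_that("SD survival reduces to background hazard without killing", {
  p <- exposure_profile(0, 5)
  s <- survival_sd(p, guts_params_sd(hb = 0.01, kd = 1, z = 1, b = 0), c(0, 10))
  expect_equal(s$probabilities, c(1, exp(-0.1)), tolerance = 1e-10)
  # sub-threshold damage: same reduction
  s2 <- survival_sd(exposure_profile(0, 0.5),
                    guts_params_sd(hb = 0.02, kd = 2, z = 1, b = 3), c(0, 4, 8))
  expect_equal(s2$probabilities, exp(-0.02 * c(0, 4, 8)), tolerance = 1e-10)
})

test_that("SD survival matches the closed form for fast kinetics", {
  s <- survival_sd(exposure_profile(0, 2),
                   guts_params_sd(hb = 0, kd = 1e3, z = 1, b = 0.5), c(0, 2))
  expect_equal(s$probabilities[2], exp(-1), tolerance = 1e-3)
})

test_that("SD hazard integral is exact on a hand-computed crossing case", {
  # C = 2 constant, kd = 1, z = 1: D crosses z at t* = log(2);
  # int_0^t (D - z) = (C - z)(t - t*) + C (exp(-t) - exp(-t*)) for t > t*
  tt <- 3
  tstar <- log(2)
  integral <- (2 - 1) * (tt - tstar) + 2 * (exp(-tt) - exp(-tstar))
  s <- survival_sd(exposure_profile(0, 2),
                   guts_params_sd(hb = 0, kd = 1, z = 1, b = 0.7), c(0, tt))
  expect_equal(s$probabilities[2], exp(-0.7 * integral), tolerance = 1e-10)
})

test_that("IT survival follows the log-logistic running-max form", {
  D <- 2 * (1 - exp(-1))
  s <- survival_it(exposure_profile(0, 2),
                   guts_params_it(hb = 0, kd = 1, mw = 1, beta = 2), c(0, 1))
  expect_equal(s$probabilities[2], 1 - 1 / (1 + D^(-2)), tolerance = 1e-12)
  expect_equal(s$probabilities[2], 0.38492, tolerance = 1e-3)
  # running-max damage equal to the median threshold halves survival
  s2 <- survival_it(exposure_profile(0, 1),
                    guts_params_it(hb = 0, kd = 1e4, mw = 1, beta = 3), c(0, 5))
  expect_equal(s2$probabilities[2], 0.5, tolerance = 1e-3)
  # mw -> Inf: no susceptible fraction, background hazard only
  s3 <- survival_it(exposure_profile(0, 10),
                    guts_params_it(hb = 0.03, kd = 1, mw = Inf, beta = 2), c(0, 6))
  expect_equal(s3$probabilities[2], exp(-0.18), tolerance = 1e-10)
})

test_that("IT survival is non-increasing even after exposure stops", {
  pulse <- exposure_profile(c(0, 1, 1.001, 6), c(4, 4, 0, 0))
  s <- survival_it(pulse, guts_params_it(hb = 0, kd = 0.8, mw = 1.5, beta = 2), 0:6)
  expect_true(all(diff(s$probabilities) <= 1e-12))
  # after the pulse the running max is frozen: survival stays flat (hb = 0)
  expect_equal(s$probabilities[4], s$probabilities[7], tolerance = 1e-10)
})

test_that("survival is non-increasing under pointwise exposure increase", {
  for (s in 1:5) {
    prof <- random_profile(700 + s)
    prof_hi <- exposure_profile(prof$times, prof$concentrations * 1.5,
                                prof$interpolation)
    tt <- seq(0, max(prof$times) + 1, length.out = 6)
    psd <- guts_params_sd(0.01, 0.7, 0.8, 0.5)
    pit <- guts_params_it(0.01, 0.7, 0.9, 2.5)
    expect_true(all(survival_sd(prof_hi, psd, tt)$probabilities <=
                    survival_sd(prof, psd, tt)$probabilities + 1e-12))
    expect_true(all(survival_it(prof_hi, pit, tt)$probabilities <=
                    survival_it(prof, pit, tt)$probabilities + 1e-12))
  }
})

test_that("survivor-count sampling honours its contracts", {
  curve1 <- survival_curve(0:3, rep(1, 4))
  expect_equal(sample_survival_counts(curve1, 12, seed = 1), rep(12L, 4))
  curve0 <- survival_curve(0:3, c(1, 0, 0, 0))
  expect_equal(sample_survival_counts(curve0, 12, seed = 1), c(12L, 0L, 0L, 0L))
  curve <- survival_curve(0:4, c(1, 0.9, 0.7, 0.6, 0.5))
  a <- sample_survival_counts(curve, 30, seed = 99)
  b <- sample_survival_counts(curve, 30, seed = 99)
  expect_identical(a, b)                            # bit-reproducible
  expect_true(all(diff(a) <= 0))
})

test_that("sampled counts have the binomial marginal mean", {
  curve <- survival_curve(c(0, 1), c(1, 0.6))
  n0 <- 50
  draws <- vapply(1:4000, function(i)
    sample_survival_counts(curve, n0, seed = i)[2], integer(1))
  se <- sqrt(n0 * 0.6 * 0.4 / 4000)
  expect_lt(abs(mean(draws) - 30), 3 * se + 1e-9)
})
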