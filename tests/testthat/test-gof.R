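perfect_fixture <- function() {
  data.frame(treatment = rep(c("A", "B"), each = 3), time = rep(1:3, 2),
             obs = c(9, 7, 5, 10, 8, 6), median = c(9, 7, 5, 10, 8, 6),
             lower = c(8, 6, 4, 9, 7, 5), upper = c(10, 8, 6, 10, 9, 7),
             n0 = 10, s_median = c(9, 7, 5, 10, 8, 6) / 10)
}

test_that("NRMSE matches its worked example and brute force", {
  pf <- paired_series(data.frame(treatment = "A", time = 1:4,
                                 obs = c(10, 8, 5, 2), median = c(9, 8, 6, 2),
                                 lower = 0, upper = 10, n0 = 10),
                      drop_t0 = FALSE)
  expect_equal(nrmse(pf), 100 * sqrt(2 / 4) / 6.25, tolerance = 1e-12)
  expect_equal(nrmse(pf), 11.3137, tolerance = 1e-4)
  # scale invariance
  pf2 <- pf; pf2$obs <- pf2$obs * 3; pf2$pred <- pf2$pred * 3; pf2$n0 <- 30
  expect_equal(nrmse(pf2), nrmse(pf), tolerance = 1e-12)
  pf0 <- pf; pf0$obs <- 0
  expect_error(nrmse(pf0), "normalization undefined")
})

test_that("SPPE computes per-treatment errors with zero-clipping", {
  r <- sppe(c(10, 5, 0), c(8, 6, 1), c(10, 10, 10))
  expect_equal(r$per_treatment, c(20, -10, -10))
  expect_equal(r$sppe_min, -10)
  expect_equal(r$sppe_max, 20)
  # consistent overestimation of survival: max clipped to 0
  r2 <- sppe(c(9, 4), c(10, 6), c(10, 10))
  expect_equal(r2$sppe_max, 0)
  expect_equal(r2$sppe_min, -20)
  # perfect end predictions
  r3 <- sppe(c(5, 5), c(5, 5), c(10, 10))
  expect_equal(c(r3$sppe_min, r3$sppe_max), c(0, 0))
})

test_that("PPC counts interval membership with closed bounds", {
  pf <- paired_series(data.frame(treatment = "A", time = 1:10,
                                 obs = c(5, 5, 5, 5, 5, 5, 5, 5, 0, 10),
                                 median = 5, lower = 4, upper = 6, n0 = 10),
                      drop_t0 = FALSE)
  expect_equal(ppc(pf), 80)
  # boundary value counts as inside
  pfb <- paired_series(data.frame(treatment = "A", time = 1, obs = 4,
                                  median = 5, lower = 4, upper = 6, n0 = 10),
                       drop_t0 = FALSE)
  expect_equal(ppc(pfb), 100)
})

test_that("Nagelkerke pseudo-R2 matches its worked example and bounds", {
  expect_equal(nagelkerke_r2(c(9, 1), c(10, 10), c(0.9, 0.1)), 0.99946,
               tolerance = 1e-4)
  # model equal to the null model scores zero
  expect_equal(nagelkerke_r2(c(6, 4), c(10, 10), c(0.5, 0.5)), 0,
               tolerance = 1e-12)
  expect_warning(r <- nagelkerke_r2(c(10, 0), c(10, 10), c(0, 1)), "zero")
  expect_identical(r, -Inf)
})

test_that("metric rescaling maps to the unit interval as specified", {
  expect_equal(scale_metric("nrmse", 0), 1)
  expect_equal(scale_metric("nrmse", 150), 0)
  expect_equal(scale_metric("ppc", 100), 1)
  expect_equal(scale_metric("sppe_min", -35.5), 0.645)
  expect_equal(scale_metric("sppe_max", 8.45), 0.9155)
  expect_equal(scale_metric("pseudo_r2", -0.3), 0)
  expect_error(scale_metric("nope", 1), "unknown metric")
})

test_that("combined GoF averages or minimizes the selected members", {
  sc <- c(nrmse = 0.8, ppc = 0.9, sppe_min = 0.6, sppe_max = 1.0)
  expect_equal(combine_gof(sc, "average"), 0.825)
  expect_equal(combine_gof(sc, "minimum"), 0.6)
  expect_error(combine_gof(sc[-1], "average"), "missing")
  for (s in 1:20) {
    set.seed(s)
    v <- runif(4)
    names(v) <- names(sc)
    expect_lte(combine_gof(v, "minimum"), combine_gof(v, "average"))
  }
})

test_that("a perfect fit scores perfectly on every metric", {
  pf <- paired_series(perfect_fixture())
  g <- gof_metrics(pf)
  expect_equal(g$raw$nrmse, 0)
  expect_equal(g$raw$ppc, 100)
  expect_equal(g$raw$sppe_min, 0)
  expect_equal(g$raw$sppe_max, 0)
  expect_equal(unname(g$scaled[c("nrmse", "ppc", "sppe_min", "sppe_max")]),
               rep(1, 4))
  expect_equal(g$avg_gof, 1)
  expect_equal(g$min_gof, 1)
})

test_that("uniform prediction bias degrades NRMSE, SPPE and combined GoF", {
  base <- perfect_fixture()
  pf <- paired_series(base)
  g0 <- gof_metrics(pf)
  for (bias in c(1, 2, 3)) {
    biased <- base
    biased$median <- pmax(0, biased$median - bias)
    biased$s_median <- biased$median / biased$n0
    gb <- gof_metrics(paired_series(biased))
    expect_gt(gb$raw$nrmse, g0$raw$nrmse)
    expect_gt(abs(gb$raw$sppe_max), abs(g0$raw$sppe_max))
    expect_lte(gb$avg_gof, g0$avg_gof)
    g0 <- gb
  }
})

test_that("metrics agree with naive brute-force loops on random fixtures", {
  for (s in 1:200) {
    fx <- random_gof_fixture(s)
    pf <- paired_series(fx, drop_t0 = FALSE)
    expect_equal(nrmse(pf), nrmse_brute(fx$obs, fx$median), tolerance = 1e-12)
    expect_equal(ppc(pf), ppc_brute(fx$obs, fx$lower, fx$upper),
                 tolerance = 1e-12)
    ends <- do.call(rbind, lapply(split(fx, fx$treatment), function(d)
      d[which.max(d$time), ]))
    sb <- sppe_brute(ends$obs, ends$median, ends$n0)
    sp <- sppe(ends$obs, ends$median, ends$n0)
    expect_equal(sp$sppe_min, sb$mn, tolerance = 1e-12)
    expect_equal(sp$sppe_max, sb$mx, tolerance = 1e-12)
    expect_equal(nagelkerke_r2(ends$obs, ends$n0, ends$s_median),
                 nagelkerke_brute(ends$obs, ends$n0, ends$s_median),
                 tolerance = 1e-10)
  }
})

test_that("fit selection applies the effect and treatment-count filters", {
  mk_fit <- function(id, effects, gof = 0.8, n_treat = length(effects)) {
    list(fit_id = id, end_mortality = effects,
         gof = list(avg_gof = gof))
  }
  fits <- list(mk_fit("a", c(0.9, 0.1)), mk_fit("b", c(0.8, 0.2)),
               mk_fit("c", c(0.7, 0.0)), mk_fit("d", c(0.65, 0.3)),
               mk_fit("e", c(0.5, 0.2)), mk_fit("f", c(0.2, 0.1)))
  kept <- select_fits(fits, stratify = FALSE)
  expect_equal(vapply(kept, `[[`, character(1), "fit_id"), c("a", "b", "c"))
  # boundary: exactly 70% effect is retained (inclusive rule)
  expect_equal(length(select_fits(list(mk_fit("x", c(0.7, 0))),
                                  stratify = FALSE)), 1L)
  expect_warning(kept2 <- select_fits(list(mk_fit("y", c(0.65, 0))),
                                      stratify = FALSE), "no fits")
  expect_length(kept2, 0)
  # single-treatment experiments are always excluded
  expect_warning(expect_length(
    select_fits(list(mk_fit("z", 0.95)), stratify = FALSE), 0))
})

test_that("stratified subsampling balances GoF bins deterministically", {
  fits <- lapply(1:40, function(i)
    list(fit_id = i, end_mortality = c(0.9, 0.1),
         gof = list(avg_gof = (i %% 10) / 10 + 0.05)))
  k1 <- select_fits(fits, n_bins = 5, seed = 7)
  k2 <- select_fits(fits, n_bins = 5, seed = 7)
  expect_identical(vapply(k1, `[[`, numeric(1), "fit_id"),
                   vapply(k2, `[[`, numeric(1), "fit_id"))
  gof <- vapply(k1, function(f) f$gof$avg_gof, numeric(1))
  bins <- table(cut(gof, seq(0, 1, 0.2)))
  expect_true(max(bins) - min(bins[bins > 0]) <= 1)
})
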