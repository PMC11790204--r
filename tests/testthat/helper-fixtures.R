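# shared fixtures and independent brute-force oracles

# adaptive numerical integration of the damage ODE, segment by segment so
# the integrator never steps across a concentration kink
numeric_damage <- function(profile, kd, times) {
  f <- if (profile$interpolation == "constant") {
    if (length(profile$times) == 1L) {
      function(t) rep(profile$concentrations, length(t))
    } else {
      approxfun(profile$times, profile$concentrations, method = "constant",
                rule = 2, f = 0)
    }
  } else {
    if (length(profile$times) == 1L) {
      function(t) rep(profile$concentrations, length(t))
    } else {
      approxfun(profile$times, profile$concentrations, rule = 2)
    }
  }
  upto <- max(times)
  breaks <- sort(unique(c(profile$times[profile$times > 0 & profile$times < upto],
                          times[times > 0], upto)))
  D <- 0
  out <- numeric(length(times))
  prev <- 0
  for (b in breaks) {
    sol <- deSolve::ode(c(D = unname(D)), c(prev, b),
                        function(t, y, p) list(kd * (f(t) - y[1])), NULL,
                        rtol = 1e-11, atol = 1e-13)
    D <- unname(sol[nrow(sol), 2])
    if (b %in% times) out[times == b] <- D
    prev <- b
  }
  out
}

random_profile <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  exposure_profile(cumsum(runif(n, 0.3, 2)) - 0.3,
                   runif(n, 0, 5),
                   sample(c("linear", "constant"), 1))
}

# naive loop re-implementations of the metric formulas
nrmse_brute <- function(obs, pred) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (obs[i] - pred[i])^2
  100 * sqrt(s / length(obs)) / mean(obs)
}

ppc_brute <- function(obs, lower, upper) {
  k <- 0
  for (i in seq_along(obs)) if (obs[i] >= lower[i] && obs[i] <= upper[i]) k <- k + 1
  100 * k / length(obs)
}

sppe_brute <- function(obs_end, pred_end, n0) {
  per <- numeric(length(obs_end))
  for (k in seq_along(obs_end)) per[k] <- 100 * (obs_end[k] - pred_end[k]) / n0[k]
  list(mn = min(c(per, 0)), mx = max(c(per, 0)), per = per)
}

nagelkerke_brute <- function(obs_end, n0, p_pred) {
  p0 <- sum(obs_end) / sum(n0)
  L0 <- 1; LM <- 1
  for (k in seq_along(obs_end)) {
    L0 <- L0 * dbinom(obs_end[k], n0[k], p0)
    LM <- LM * dbinom(obs_end[k], n0[k], p_pred[k])
  }
  n <- length(obs_end)
  (1 - (L0 / LM)^(2 / n)) / (1 - L0^(2 / n))
}

# random paired-series fixture with end data
random_gof_fixture <- function(seed) {
  set.seed(seed)
  n_tr <- sample(2:4, 1)
  n_t <- sample(3:5, 1)
  n0 <- sample(c(10L, 20L), 1)
  rows <- do.call(rbind, lapply(seq_len(n_tr), function(k) {
    # keep the first treatment's counts strictly inside (0, n0) so the
    # pseudo-R2 null model is never saturated (p0 of exactly 0 or 1)
    obs <- if (k == 1L) sort(sample(1:(n0 - 1L), n_t, replace = TRUE),
                             decreasing = TRUE)
           else sort(sample(0:n0, n_t, replace = TRUE), decreasing = TRUE)
    pred <- pmax(0, pmin(n0, obs + sample(-2:2, n_t, replace = TRUE)))
    data.frame(treatment = sprintf("T%d", k), time = seq_len(n_t),
               obs = obs, median = pred,
               lower = pmax(0, pred - sample(0:3, n_t, replace = TRUE)),
               upper = pmin(n0, pred + sample(0:3, n_t, replace = TRUE)),
               n0 = n0, s_median = pmin(1 - 1e-9, pmax(1e-9, pred / n0)))
  }))
  rows
}

# fixed-effect-only ordinal records generated from a known single-predictor
# cumulative probit model
make_screen_records <- function(seed, n_ev = 20L, per_ev = 15L, n_fit = 40L,
                                members = c("nrmse_s", "ppc_s", "sppe_min_s"),
                                beta = -6, acc50 = 0.5) {
  set.seed(seed)
  gt <- data.frame(fit_id = sprintf("f%03d", seq_len(n_fit)),
                   nrmse_s = runif(n_fit), ppc_s = runif(n_fit),
                   sppe_min_s = runif(n_fit), sppe_max_s = runif(n_fit),
                   pseudo_r2_s = runif(n_fit))
  rows <- gt[sample(n_fit, n_ev * per_ev, replace = TRUE), ]
  rows$evaluator_id <- rep(sprintf("e%03d", seq_len(n_ev)), each = per_ev)
  rows$role <- "calibration"
  rows$representation <- "TS"
  rows$experience <- 3L
  rows$affiliation <- "academia"
  truegof <- if (length(members) == 1L) rows[[members]]
             else rowMeans(rows[, members])
  cuts <- beta * acc50 + c(-2, -1, 0, 1, 2)
  cum <- sapply(cuts, function(cp) pnorm(cp - beta * truegof))
  rows$score <- as.integer(1 + rowSums(runif(nrow(rows)) > cum))
  rownames(rows) <- NULL
  rows
}
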