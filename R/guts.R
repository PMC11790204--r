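#' GUTS-RED parameter sets
#'
#' Constructors for the two reduced-GUTS death mechanisms. Stochastic death
#' (SD) assumes every organism shares a damage threshold `z` above which a
#' hazard proportional to the exceedance (killing rate `b`) applies.
#' Individual tolerance (IT) assumes organism-specific thresholds drawn from
#' a log-logistic distribution with median `mw` and shape `beta`; an organism
#' dies once its running-maximum damage exceeds its own threshold. Both share
#' a background hazard rate `hb` and the dominant rate constant `kd` of the
#' damage dynamic. Time unit is days throughout; concentration units are
#' carried through from the exposure profile.
#'
#' @param hb background hazard rate (1/day), `>= 0`.
#' @param kd dominant rate constant (1/day), `> 0`.
#' @param z damage threshold (exposure units), `>= 0` (SD).
#' @param b killing rate (1/(exposure unit day)), `>= 0` (SD).
#' @param mw median of the threshold distribution (exposure units), `> 0` (IT).
#' @param beta log-logistic shape parameter, `> 0` (IT).
#' @return A parameter object of class `guts_params_sd` or `guts_params_it`.
#' @export
guts_params_sd <- function(hb, kd, z, b) {
  assert_that(all(is.finite(c(hb, kd, z, b))), "SD parameters must be finite")
  assert_that(hb >= 0 && z >= 0 && b >= 0, "SD parameters must be non-negative")
  assert_that(kd > 0, "kd must be positive")
  structure(list(hb = hb, kd = kd, z = z, b = b),
            class = c("guts_params_sd", "guts_params"))
}

#' @rdname guts_params_sd
#' @export
guts_params_it <- function(hb, kd, mw, beta) {
  assert_that(is.finite(hb) && is.finite(kd) && is.finite(beta),
              "IT parameters must be finite")
  assert_that(hb >= 0, "hb must be non-negative")
  assert_that(kd > 0, "kd must be positive")
  assert_that(mw > 0, "mw must be positive")   # Inf allowed: no susceptible fraction
  assert_that(beta > 0, "beta must be positive")
  structure(list(hb = hb, kd = kd, mw = mw, beta = beta),
            class = c("guts_params_it", "guts_params"))
}

#' Survival curve container
#'
#' @param times time points (days), non-decreasing.
#' @param probabilities survival probabilities in `[0, 1]`, non-increasing.
#' @return object of class `survival_curve`.
#' @export
survival_curve <- function(times, probabilities) {
  assert_that(length(times) == length(probabilities), "length mismatch")
  assert_that(all(probabilities >= -1e-12 & probabilities <= 1 + 1e-12),
              "probabilities must lie in [0, 1]")
  assert_that(all(diff(probabilities) <= 1e-12),
              "survival probabilities must be non-increasing")
  probabilities <- pmin(pmax(probabilities, 0), 1)
  structure(list(times = times, probabilities = probabilities),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d time(s), S(end) = %.4f\n",
              length(x$times), x$probabilities[length(x$probabilities)]))
  invisible(x)
}

# Per-segment damage decomposition on [0, upto]:
# on segment i, D(t0 + tau) = M + B*tau + K*exp(-kd*tau), tau in [0, L].
damage_decomposition <- function(profile, kd, upto, extra = numeric()) {
  seg <- profile_segments(profile, upto, extra = extra)
  n <- length(seg$t0)
  M <- K <- D0 <- D1 <- numeric(n)
  D <- 0
  for (i in seq_len(n)) {
    L <- seg$t1[i] - seg$t0[i]
    B <- seg$slope[i]
    M[i] <- seg$c0[i] - B / kd
    K[i] <- D - M[i]
    D0[i] <- D
    D <- M[i] + B * L + K[i] * exp(-kd * L)
    D1[i] <- D
  }
  list(t0 = seg$t0, t1 = seg$t1, L = seg$t1 - seg$t0, B = seg$slope,
       M = M, K = K, D0 = D0, D1 = D1, kd = kd)
}

# g(tau) = (M - z) + B*tau + K*exp(-kd*tau) on one segment; antiderivative
seg_g <- function(tau, M, B, K, kd, z) (M - z) + B * tau + K * exp(-kd * tau)
seg_G <- function(tau, M, B, K, kd, z) (M - z) * tau + B * tau^2 / 2 - (K / kd) * exp(-kd * tau)

# crossing time of g = 0 on a monotone piece [a, b] with opposite endpoint signs
seg_crossing <- function(a, b, M, B, K, kd, z) {
  if (B == 0) {
    # closed form: exp(-kd tau) = (z - M)/K
    r <- (z - M) / K
    if (r > 0) return(-log(r) / kd)
  }
  stats::uniroot(seg_g, c(a, b), M = M, B = B, K = K, kd = kd, z = z,
                 tol = 1e-13 * max(1, b))$root
}

# exact integral of max(0, D(tau) - z) over [0, L] for one segment
seg_exceedance_integral <- function(L, M, B, K, kd, z) {
  # split at the unique critical point of g (if interior) into monotone pieces
  pieces <- c(0, L)
  if (B != 0 && K != 0) {
    r <- B / (kd * K)
    if (r > 0) {
      tc <- -log(r) / kd
      if (tc > 0 && tc < L) pieces <- c(0, tc, L)
    }
  }
  total <- 0
  for (j in seq_len(length(pieces) - 1L)) {
    a <- pieces[j]; b <- pieces[j + 1L]
    ga <- seg_g(a, M, B, K, kd, z); gb <- seg_g(b, M, B, K, kd, z)
    if (ga <= 0 && gb <= 0) next
    lo <- a; hi <- b
    if (ga < 0 && gb > 0) lo <- seg_crossing(a, b, M, B, K, kd, z)
    if (ga > 0 && gb < 0) hi <- seg_crossing(a, b, M, B, K, kd, z)
    total <- total + (seg_G(hi, M, B, K, kd, z) - seg_G(lo, M, B, K, kd, z))
  }
  max(total, 0)
}

# running maximum of damage at each segment endpoint
seg_running_max <- function(dec) {
  n <- length(dec$L)
  segmax <- numeric(n)
  for (i in seq_len(n)) {
    m <- max(dec$D0[i], dec$D1[i])
    B <- dec$B[i]; K <- dec$K[i]; kd <- dec$kd
    if (B != 0 && K != 0) {
      r <- B / (kd * K)
      if (r > 0) {
        tc <- -log(r) / kd
        if (tc > 0 && tc < dec$L[i]) m <- max(m, dec$M[i] + B * tc + B / kd)
      }
    }
    segmax[i] <- m
  }
  cummax(segmax)
}

prep_times <- function(times) {
  times <- as.numeric(times)
  assert_that(all(is.finite(times)) && all(times >= 0),
              "times must be finite and >= 0")
  assert_that(!is.unsorted(times), "times must be non-decreasing")
  times
}

#' GUTS-RED-SD survival probabilities
#'
#' Survival under the stochastic-death mechanism,
#' `S(t) = exp(-hb t - b * int_0^t max(0, D(tau) - z) dtau)`.
#' The hazard integral is evaluated exactly on every exposure segment (the
#' damage is exponential-affine there, and threshold crossings are solved per
#' monotone piece), so no quadrature step size is involved.
#'
#' @param profile an [exposure_profile()].
#' @param params a [guts_params_sd()].
#' @param times non-decreasing requested times (days).
#' @return a [survival_curve()].
#' @export
survival_sd <- function(profile, params, times) {
  assert_that(inherits(params, "guts_params_sd"), "params must be guts_params_sd")
  times <- prep_times(times)
  ut <- unique(times)
  S <- rep(1, length(ut))
  pos <- ut > 0
  if (any(pos) && (params$b > 0 || params$hb > 0)) {
    haz <- numeric(length(ut))
    if (params$b > 0) {
      dec <- damage_decomposition(profile, params$kd, max(ut), extra = ut)
      segint <- vapply(seq_along(dec$L), function(i)
        seg_exceedance_integral(dec$L[i], dec$M[i], dec$B[i], dec$K[i],
                                dec$kd, params$z), numeric(1))
      cumint <- cumsum(segint)
      haz[pos] <- params$b * cumint[match(ut[pos], dec$t1)]
    }
    S <- exp(-(params$hb * ut + haz))
  } else if (params$hb > 0) {
    S <- exp(-params$hb * ut)
  }
  survival_curve(times, S[match(times, ut)])
}

#' GUTS-RED-IT survival probabilities
#'
#' Survival under the individual-tolerance mechanism,
#' `S(t) = (1 - F(max_{tau <= t} D(tau))) * exp(-hb t)` with log-logistic
#' threshold distribution `F(x) = 1 / (1 + (x / mw)^(-beta))`, `F(0) = 0`.
#' The running maximum of damage is located exactly (damage is unimodal per
#' segment, with a closed-form interior critical point).
#'
#' @inheritParams survival_sd
#' @param params a [guts_params_it()].
#' @return a [survival_curve()].
#' @export
survival_it <- function(profile, params, times) {
  assert_that(inherits(params, "guts_params_it"), "params must be guts_params_it")
  times <- prep_times(times)
  ut <- unique(times)
  dmax <- numeric(length(ut))
  pos <- ut > 0
  if (any(pos)) {
    dec <- damage_decomposition(profile, params$kd, max(ut), extra = ut)
    rmax <- seg_running_max(dec)
    dmax[pos] <- rmax[match(ut[pos], dec$t1)]
  }
  Fx <- ifelse(dmax <= 0, 0,
               if (is.infinite(params$mw)) 0
               else 1 / (1 + (dmax / params$mw)^(-params$beta)))
  S <- (1 - Fx) * exp(-params$hb * ut)
  survival_curve(times, S[match(times, ut)])
}

#' Sample survivor counts along a survival curve
#'
#' Draws a non-increasing survivor trajectory whose marginal distribution at
#' each time is `Binomial(n0, S(t))`, by chaining conditional binomial deaths
#' between consecutive observation times.
#'
#' @param curve a [survival_curve()] (first time should be the start of the
#'   test with `S = 1`).
#' @param n0 initial number of organisms, `>= 1`.
#' @param seed integer RNG seed (fixed seed gives bit-identical counts).
#' @return integer vector of survivor counts, same length as `curve$times`.
#' @export
sample_survival_counts <- function(curve, n0, seed) {
  assert_that(inherits(curve, "survival_curve"), "curve must be a survival_curve")
  assert_that(n0 >= 1, "n0 must be >= 1")
  S <- curve$probabilities
  with_seed(seed, {
    counts <- integer(length(S))
    n0 <- as.integer(n0)
    counts[1] <- if (curve$times[1] == 0) n0 else stats::rbinom(1, n0, S[1])
    prev_S <- if (curve$times[1] == 0) 1 else S[1]
    y <- counts[1]
    for (i in seq_along(S)[-1]) {
      ratio <- if (prev_S <= 0) 0 else min(S[i] / prev_S, 1)
      y <- stats::rbinom(1, y, ratio)
      counts[i] <- y
      prev_S <- S[i]
    }
    counts
  })
}
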