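#' Piecewise exposure profile
#'
#' Represents the external concentration `Cw(t)` an organism experiences in a
#' toxicity-test treatment, as a piecewise function of time. Two
#' interpolation rules are supported: `"linear"` segments (measured-profile
#' practice, the default) and `"constant"` segments (media-renewal designs,
#' where the concentration holds until the next renewal). Beyond the last
#' time point the last concentration is held, so a profile ending in 0
#' contributes no further exposure.
#'
#' @param times strictly increasing time points (days).
#' @param concentrations non-negative finite concentrations at `times`
#'   (exposure units are carried through unchanged).
#' @param interpolation `"linear"` or `"constant"`.
#' @return An object of class `exposure_profile`.
#' @examples
#' pulse <- exposure_profile(c(0, 1, 1.0001, 3), c(5, 5, 0, 0))
#' constant <- exposure_profile(0, 2)
#' @export
exposure_profile <- function(times, concentrations,
                             interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  assert_that(length(times) >= 1L, "profile needs at least one time point")
  assert_that(length(times) == length(concentrations),
              "times and concentrations must have equal length")
  assert_that(all(is.finite(times)) && all(is.finite(concentrations)),
              "times and concentrations must be finite")
  assert_that(all(diff(times) > 0), "profile times must be strictly increasing")
  assert_that(all(concentrations >= 0), "concentrations must be non-negative")
  structure(
    list(times = times, concentrations = concentrations,
         interpolation = interpolation),
    class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("<exposure_profile> %d point(s), %s segments, peak %.4g\n",
              length(x$times), x$interpolation, max(x$concentrations)))
  invisible(x)
}

#' Concentration at arbitrary times
#'
#' @param profile an [exposure_profile()].
#' @param t numeric times (days).
#' @return concentrations at `t` under the profile's interpolation rule.
#' @export
conc_at <- function(profile, t) {
  tt <- profile$times; cc <- profile$concentrations
  if (length(tt) == 1L) return(rep(cc, length(t)))
  method <- if (profile$interpolation == "constant") "constant" else "linear"
  f <- stats::approxfun(tt, cc, method = method, rule = 2, f = 0)
  f(t)
}

# Segment table for integration on [0, upto]: rows (t0, t1, c0, slope) where
# concentration on the segment is c0 + slope * (t - t0). `extra` times are
# inserted as additional breakpoints so requested output times always fall on
# segment boundaries. Before the first profile time and after the last one
# the concentration is held constant.
profile_segments <- function(profile, upto, extra = numeric()) {
  breaks <- sort(unique(c(0, upto, extra[extra > 0 & extra < upto],
                          profile$times[profile$times > 0 & profile$times < upto])))
  t0 <- breaks[-length(breaks)]
  t1 <- breaks[-1L]
  if (profile$interpolation == "constant" || length(profile$times) == 1L) {
    c0 <- conc_at(profile, t0)
    slope <- rep(0, length(t0))
  } else {
    c0 <- conc_at(profile, t0)
    c1 <- conc_at(profile, t1)
    slope <- (c1 - c0) / (t1 - t0)
  }
  list(t0 = t0, t1 = t1, c0 = c0, slope = slope)
}

#' Scaled damage under first-order kinetics
#'
#' Solves the reduced-GUTS damage dynamic `dD/dt = kd (Cw(t) - D)`, `D(0) = 0`
#' piecewise-analytically: on every segment the concentration is affine in
#' time, so the damage is exponential-affine and is propagated in closed form
#' with no quadrature error. The dominant rate constant `kd` lumps
#' toxicokinetics and damage repair.
#'
#' @param profile an [exposure_profile()].
#' @param kd dominant rate constant (1/day), `> 0`.
#' @param times strictly increasing requested times (days), `>= 0`.
#' @return numeric vector `D(times)` in exposure units.
#' @examples
#' p <- exposure_profile(0, 2)
#' damage_series(p, kd = 0.5, times = 2)  # 2 * (1 - exp(-1))
#' @export
damage_series <- function(profile, kd, times) {
  assert_that(inherits(profile, "exposure_profile"), "profile must be an exposure_profile")
  assert_that(is.numeric(kd) && length(kd) == 1L && is.finite(kd) && kd > 0,
              "kd must be a single positive number")
  times <- as.numeric(times)
  assert_that(all(is.finite(times)) && all(times >= 0), "times must be finite and >= 0")
  assert_that(!is.unsorted(times, strictly = TRUE),
              "requested times must be strictly increasing")
  out <- numeric(length(times))
  pos <- times > 0
  if (!any(pos)) return(out)
  upto <- max(times)
  seg <- profile_segments(profile, upto, extra = times)
  D <- 0
  # endpoint damage per segment, then pick requested breakpoints
  ends <- numeric(length(seg$t0))
  for (i in seq_along(seg$t0)) {
    L <- seg$t1[i] - seg$t0[i]
    B <- seg$slope[i]
    M <- seg$c0[i] - B / kd          # D(tau) = M + B*tau + K*exp(-kd*tau)
    K <- D - M
    D <- M + B * L + K * exp(-kd * L)
    ends[i] <- D
  }
  idx <- match(times[pos], seg$t1)
  out[pos] <- ends[idx]
  out
}
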