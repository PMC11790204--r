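#' Wilson score interval for a binomial proportion
#'
#' Centre `(p + z^2/2n) / (1 + z^2/n)` with half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, `z` the standard-normal
#' quantile of the confidence level. Used as the error bar on observed
#' survival proportions in fit images.
#'
#' @param k number of successes (survivors), `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param confidence confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `confidence`.
#' @examples
#' wilson_interval(5, 10)  # (0.2366, 0.7634)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  assert_that(all(n >= 1) && all(k >= 0) && all(k <= n),
              "need 0 <= k <= n and n >= 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = pmax(0, centre - half),
       upper = pmin(1, centre + half), confidence = confidence)
}
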