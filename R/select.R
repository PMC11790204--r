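#' Fit-selection filters and GoF stratification
#'
#' Mirrors the survey's realism filters: a fit is retained only if at least
#' one treatment shows an end-of-test effect (mortality) of at least
#' `min_effect` (inclusive), and experiments with a single treatment are
#' excluded (such data would not be used to evaluate model performance in
#' practice). The survivors are then stratified into equal-width bins of the
#' combined GoF and subsampled to approximately equal counts per bin, so all
#' fit-quality levels are covered.
#'
#' @param fits list of fit objects; each must carry `$gof` (a
#'   [gof_metrics()]) and either `$end_mortality` (numeric per treatment) or
#'   `$dataset` (a [survival_dataset()], from which end mortality
#'   `1 - y_end/n0` and the treatment count are derived).
#' @param min_effect minimum required maximum end mortality (default 0.70).
#' @param min_treatments minimum treatments per fit (default 2).
#' @param n_bins number of equal-width `avg_gof` bins on `[0, 1]`.
#' @param per_bin fits retained per bin; `NULL` keeps the minimum occupied
#'   bin count (balanced design).
#' @param stratify apply the seeded stratified subsampling (default `TRUE`).
#' @param seed integer seed for the subsampling.
#' @return the retained subset of `fits` (possibly empty, with a warning).
#' @export
select_fits <- function(fits, min_effect = 0.70, min_treatments = 2L,
                        n_bins = 5L, per_bin = NULL, stratify = TRUE,
                        seed = 1L) {
  keep <- vapply(fits, function(f) {
    mort <- f$end_mortality
    n_tr <- NULL
    if (is.null(mort)) {
      trs <- all_treatments(f$dataset)
      mort <- vapply(trs, function(tr)
        1 - tr$survivors[length(tr$survivors)] / tr$n0, numeric(1))
      n_tr <- length(trs)
    }
    n_tr <- n_tr %||% length(mort)
    n_tr >= min_treatments && max(mort) >= min_effect
  }, logical(1))
  fits <- fits[keep]
  if (length(fits) == 0) {
    warning("no fits retained by the effect/treatment filters")
    return(fits)
  }
  if (!stratify) return(fits)
  gof <- vapply(fits, function(f) f$gof$avg_gof, numeric(1))
  bin <- pmin(pmax(ceiling(gof * n_bins), 1L), n_bins)
  counts <- table(bin)
  target <- per_bin %||% min(counts)
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(fits), bin), function(ix) {
      if (length(ix) <= target) ix else sample(ix, target)
    }), use.names = FALSE)
  })
  fits[sort(idx)]
}
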