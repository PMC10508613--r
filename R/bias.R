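#' P-value bias induced by standard-error deflation
#'
#' Converts a reference two-sided normal p-value into the p-value that
#' results when the standard error of the underlying z-statistic is
#' multiplied by a deflation factor: the z-quantile at the reference
#' p-value is divided by the deflation and transformed back,
#' `2 * pnorm(qnorm(1 - p/2) / deflation, lower.tail = FALSE)`. With
#' deflation below 1 the biased p-value is always smaller than the
#' reference, and the relative bias grows as the reference p-value shrinks.
#'
#' @param reference_p reference (correct) two-sided p-value in `(0, 1)`.
#' @param deflation standard-error ratio in `(0, 1]`; see [se_deflation()].
#' @return The biased two-sided p-value (vectorized over both arguments).
#' @examples
#' biased_pvalue(0.05, 0.89)   # ~ 0.028
#' @export
biased_pvalue <- function(reference_p, deflation) {
  if (any(reference_p <= 0 | reference_p >= 1)) {
    stop("reference_p must be in (0, 1)")
  }
  if (any(deflation <= 0 | deflation > 1)) {
    stop("deflation must be in (0, 1]")
  }
  z <- qnorm(reference_p / 2, lower.tail = FALSE)
  2 * pnorm(z / deflation, lower.tail = FALSE)
}

#' Fold decrease between a reference and a biased p-value
#'
#' @param reference_p reference p-value in `(0, 1)`.
#' @param biased_p biased p-value in `(0, 1)`, no larger than the
#'   reference.
#' @return `reference_p / biased_p`, at least 1.
#' @examples
#' fold_decrease(0.05, biased_pvalue(0.05, 0.89))   # ~ 1.8
#' @export
fold_decrease <- function(reference_p, biased_p) {
  if (any(reference_p <= 0 | reference_p >= 1) ||
      any(biased_p >= 1)) {
    stop("p-values must be in (0, 1)")
  }
  if (any(biased_p <= 0)) stop("biased_p must be positive")
  if (any(biased_p > reference_p + 1e-15)) {
    stop("biased_p must not exceed reference_p")
  }
  reference_p / biased_p
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise threshold.
#' @param m number of tests, at least 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 14584)
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (any(m < 1)) stop("m must be at least 1")
  alpha / m
}

#' Summarize per-phenotype overlap percentages
#'
#' Arithmetic mean of the per-phenotype percentages of conditioned-test
#' (TWAS) associations confirmed by the corrected covariance test, and its
#' complement: the share of associations with insufficient evidence for a
#' genetic relationship.
#'
#' @param per_phenotype_overlap_pct percentages in `[0, 100]`.
#' @return A list with `mean_overlap_pct` and `invalid_pct`
#'   (`100 - mean_overlap_pct`).
#' @export
overlap_summary <- function(per_phenotype_overlap_pct) {
  x <- as.numeric(per_phenotype_overlap_pct)
  if (!length(x)) stop("empty overlap vector")
  if (any(x < 0 | x > 100)) stop("percentages must be in [0, 100]")
  m <- mean(x)
  list(mean_overlap_pct = m, invalid_pct = 100 - m)
}

#' Summarize a distribution of standard-error deflation values
#'
#' Mean, minimum and the 5/25/50/75/95% quantiles (type-7 linear
#' interpolation) of per-gene deflation values.
#'
#' @param deflations values in `(0, 1]`.
#' @return A named list: `mean`, `minimum`, `q5`, `q25`, `median`, `q75`,
#'   `q95`.
#' @export
deflation_quantiles <- function(deflations) {
  x <- as.numeric(deflations)
  if (!length(x)) stop("empty deflation vector")
  if (any(x <= 0 | x > 1)) stop("deflation values must be in (0, 1]")
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  list(mean = mean(x), minimum = min(x), q5 = q[1], q25 = q[2],
       median = q[3], q75 = q[4], q95 = q[5])
}

#' Tabulate the p-value bias curve
#'
#' For each deflation value and reference p-value, the biased p-value and
#' the fold decrease it represents.
#'
#' @param deflations deflation values in `(0, 1]`.
#' @param reference_p reference p-values in `(0, 1)`.
#' @return A `data.frame` with columns `reference_p`, `deflation`,
#'   `biased_p`, `fold_decrease` (one row per combination).
#' @export
bias_curve <- function(deflations, reference_p = c(0.05, 1e-4)) {
  grid <- expand.grid(reference_p = reference_p, deflation = deflations,
                      KEEP.OUT.ATTRS = FALSE)
  grid$biased_p <- biased_pvalue(grid$reference_p, grid$deflation)
  grid$fold_decrease <- grid$reference_p / grid$biased_p
  grid
}
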