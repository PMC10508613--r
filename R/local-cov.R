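#' Fit the local genetic covariance model for one gene
#'
#' The central fitting function. Given per-component effect estimates for
#' gene expression and an outcome phenotype on a shared principal-component
#' basis, estimates the 2x2 local genetic covariance matrix by the method of
#' moments: the cross term is `omega_EY = sum(delta_E * delta_Y)` (no
#' sample-overlap correction, so the sampling covariance between traits is
#' zero), and each genetic variance subtracts the known sampling-noise mass,
#' `omega_E2 = sum(delta_E^2) - K * sigma2_E`. Raw (possibly negative)
#' variance estimates are stored; truncation at zero happens only inside the
#' null variances of the tests.
#'
#' Downstream methods and tests: [univariate_test()], [rg_test()],
#' [twas_test()], [se_deflation()], [compare_tests()], plus `print()`,
#' `summary()` and `coef()`.
#'
#' @param expr [component_effects()] for the gene expression.
#' @param outcome [component_effects()] for the outcome phenotype, on the
#'   same component basis (same K, same SNP set).
#' @return An object of class `local_cov` with elements `omega_E2`,
#'   `omega_EY`, `omega_Y2`, `sigma2_E`, `sigma2_Y`, `K`, `N_E`, `N_Y`,
#'   and the two `component_effects` objects (`expr`, `outcome`).
#' @examples
#' e <- component_effects(c(0.3, 0.1), N = 100, eta2 = 0.9)
#' o <- component_effects(c(0.2, -0.1), N = 1000, eta2 = 1, trait = "outcome")
#' fit <- local_cov(e, o)
#' coef(fit)
#' @export
local_cov <- function(expr, outcome) {
  stopifnot(inherits(expr, "component_effects"),
            inherits(outcome, "component_effects"))
  if (expr$K != outcome$K) stop("component basis mismatch: K differs")
  if (!is.null(expr$snp_ids) && !is.null(outcome$snp_ids) &&
      !identical(expr$snp_ids, outcome$snp_ids)) {
    stop("component basis mismatch: SNP sets differ")
  }
  k <- expr$K
  structure(
    list(omega_E2 = sum(expr$delta^2) - k * expr$sigma2,
         omega_EY = sum(expr$delta * outcome$delta),
         omega_Y2 = sum(outcome$delta^2) - k * outcome$sigma2,
         sigma2_E = expr$sigma2, sigma2_Y = outcome$sigma2,
         K = k, N_E = expr$N, N_Y = outcome$N,
         expr = expr, outcome = outcome),
    class = "local_cov")
}

#' @export
print.local_cov <- function(x, digits = 4, ...) {
  cat(sprintf("local genetic covariance fit (K = %d, N_E = %d, N_Y = %d)\n",
              x$K, x$N_E, x$N_Y))
  print(signif(coef(x), digits))
  invisible(x)
}

#' @export
coef.local_cov <- function(object, ...) {
  c(omega_E2 = object$omega_E2, omega_EY = object$omega_EY,
    omega_Y2 = object$omega_Y2)
}

#' @export
summary.local_cov <- function(object, alpha = 0.05, ...) {
  univ <- univariate_test(object$expr)
  rg <- rg_test(object)
  twas <- twas_test(object)
  structure(
    list(fit = object, univariate = univ, rg = rg, twas = twas,
         se_deflation = se_deflation(object), alpha = alpha),
    class = "summary.local_cov")
}

#' @export
print.summary.local_cov <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  univariate (expression): F(%d, %d) = %.3f, p = %.3g\n",
              x$univariate$dof[1], x$univariate$dof[2],
              x$univariate$z_or_F, x$univariate$p))
  cat(sprintf("  corrected covariance test:  z = %+.3f, p = %.3g\n",
              x$rg$z_or_F, x$rg$p))
  cat(sprintf("  conditioned (TWAS) test:    z = %+.3f, p = %.3g\n",
              x$twas$z_or_F, x$twas$p))
  cat(sprintf("  standard-error deflation: %.3f\n", x$se_deflation))
  invisible(x)
}

#' @export
as.data.frame.summary.local_cov <- function(x, row.names = NULL,
                                            optional = FALSE,
                                            gene = NA_character_, ...) {
  f <- x$fit
  data.frame(gene = gene, K = f$K, N_E = f$N_E, N_Y = f$N_Y,
             omega_E2 = f$omega_E2, omega_Y2 = f$omega_Y2,
             omega_EY = f$omega_EY, p_univ_E = x$univariate$p,
             p_rG = x$rg$p, p_TWAS = x$twas$p,
             se_deflation = x$se_deflation,
             stringsAsFactors = FALSE, row.names = row.names)
}

cov_test <- function(statistic, se, z_or_F, p, method, dof = NA_real_) {
  structure(list(statistic = statistic, se = se, z_or_F = z_or_F,
                 p = min(max(p, 0), 1), method = method, dof = dof),
            class = "cov_test")
}

#' @export
print.cov_test <- function(x, ...) {
  lab <- switch(x$method, univariate = "F", "z")
  cat(sprintf("%s test: statistic = %.4g, %s = %.4g, p = %.4g\n",
              x$method, x$statistic, lab, x$z_or_F, x$p))
  invisible(x)
}

#' Univariate joint-association test for one trait
#'
#' F-test of the joint association of all retained components with the
#' trait, i.e. of the null that the component effect vector is zero
#' (equivalently, zero local genetic variance). With the trait scaled to
#' variance 1, the model R-squared is `sum(delta^2)` and
#' `F = (R2 / K) / ((1 - R2) / (N - 1 - K))` on `(K, N - 1 - K)` degrees of
#' freedom, the standard multiple-regression F.
#'
#' @param effects a [component_effects()] object.
#' @return A `cov_test` with the F statistic, degrees of freedom and
#'   p-value.
#' @export
univariate_test <- function(effects) {
  stopifnot(inherits(effects, "component_effects"))
  k <- effects$K
  n <- effects$N
  r2 <- sum(effects$delta^2)
  if (r2 >= 1) stop("degenerate fit: R-squared at or above 1")
  f <- (r2 / k) / ((1 - r2) / (n - 1 - k))
  p <- pf(f, k, n - 1 - k, lower.tail = FALSE)
  cov_test(statistic = r2, se = NA_real_, z_or_F = f, p = p,
           method = "univariate", dof = c(k, n - 1 - k))
}

# null variances of the two covariance tests; omega^2 terms truncated at 0
# where a variance is required
v_twas <- function(fit) sum(fit$expr$delta^2) * fit$sigma2_Y
v_rg <- function(fit) {
  fit$K * fit$sigma2_E * fit$sigma2_Y +
    max(fit$omega_E2, 0) * fit$sigma2_Y +
    fit$sigma2_E * max(fit$omega_Y2, 0)
}

#' Variance-corrected local genetic covariance test
#'
#' Tests the null of zero local genetic covariance,
#' `H0: cov(G_E, G_Y) = 0`, using the method-of-moments estimate
#' `omega_EY` with null variance
#' `V_rG = K * sigma2_E * sigma2_Y + omega_E2 * sigma2_Y + sigma2_E *
#' omega_Y2`, which accounts for sampling of both traits. Negative
#' method-of-moments variance estimates are truncated at zero inside
#' `V_rG`. The statistic is a sum of product-normal terms; for moderate to
#' large K its null distribution is well approximated by a normal, and a
#' two-sided normal p-value is returned (a warning is raised below K = 30).
#'
#' @param fit a [local_cov()] fit.
#' @return A `cov_test` with statistic `omega_EY`, its null standard error,
#'   z and two-sided p.
#' @export
rg_test <- function(fit) {
  stopifnot(inherits(fit, "local_cov"))
  if (fit$K < 30) {
    warning("K < 30: the normal approximation to the null may be inaccurate")
  }
  v <- v_rg(fit)
  if (v <= 0) stop("null variance V_rG is not positive")
  z <- fit$omega_EY / sqrt(v)
  cov_test(statistic = fit$omega_EY, se = sqrt(v), z_or_F = z,
           p = 2 * pnorm(-abs(z)), method = "rG")
}

#' Conditioned (TWAS-style) covariance test
#'
#' Tests `H0: cov(Ghat_E, G_Y) = 0`, conditioning on the estimated
#' expression component: the predicted expression `Ghat_E = W %*% delta_E`
#' is treated as fixed, exactly as in a two-stage TWAS regression of the
#' outcome on predicted expression. The test statistic is the same
#' `omega_EY` as in [rg_test()]; only the null variance differs, reducing
#' to `V_TWAS = sum(delta_E^2) * sigma2_Y`, which omits the estimation
#' uncertainty in the expression effects.
#'
#' @param fit a [local_cov()] fit.
#' @return A `cov_test` with statistic `omega_EY`, its conditional standard
#'   error, z and two-sided p.
#' @export
twas_test <- function(fit) {
  stopifnot(inherits(fit, "local_cov"))
  if (fit$K < 30) {
    warning("K < 30: the normal approximation to the null may be inaccurate")
  }
  d2 <- sum(fit$expr$delta^2)
  if (d2 == 0) stop("predicted expression component has zero variance")
  v <- d2 * fit$sigma2_Y
  z <- fit$omega_EY / sqrt(v)
  cov_test(statistic = fit$omega_EY, se = sqrt(v), z_or_F = z,
           p = 2 * pnorm(-abs(z)), method = "TWAS")
}

#' Standard-error deflation of the conditioned test
#'
#' Ratio of the conditioned (TWAS) standard error to the corrected one:
#' `sqrt(V_TWAS / (V_TWAS + sigma2_E * max(omega_Y2, 0)))`. Always in
#' `(0, 1]`, equal to 1 exactly when the (truncated) outcome genetic
#' variance is zero, and strictly decreasing in `omega_Y2` otherwise. A
#' value below 1 means the conditioned test understates its uncertainty and
#' its p-values are biased downward.
#'
#' @param fit a [local_cov()] fit.
#' @return A single number in `(0, 1]`.
#' @export
se_deflation <- function(fit) {
  stopifnot(inherits(fit, "local_cov"))
  vt <- v_twas(fit)
  if (vt <= 0) stop("predicted expression component has zero variance")
  sqrt(vt / (vt + fit$sigma2_E * max(fit$omega_Y2, 0)))
}

#' Paired conditioned and corrected p-values for one gene
#'
#' Convenience record pairing the two tests of the same `omega_EY`
#' statistic, with the deflation linking them and significance flags at a
#' threshold. Because `V_TWAS <= V_rG`, the conditioned p-value can never
#' exceed the corrected one.
#'
#' @param fit a [local_cov()] fit.
#' @param alpha significance threshold for the flags.
#' @return A one-row `data.frame` with `p_TWAS`, `p_rG`, `se_deflation`,
#'   `sig_TWAS`, `sig_rG`.
#' @export
compare_tests <- function(fit, alpha = 0.05) {
  tw <- twas_test(fit)
  rg <- rg_test(fit)
  data.frame(p_TWAS = tw$p, p_rG = rg$p, se_deflation = se_deflation(fit),
             sig_TWAS = tw$p < alpha, sig_rG = rg$p < alpha)
}
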