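#' Standardize a genotype matrix
#'
#' Mean-imputes missing entries per SNP, then centers each column to mean 0
#' and scales to sample variance 1. Monomorphic SNPs (zero variance) are an
#' error, since they carry no association information and cannot be scaled.
#'
#' @param x a [genotype_panel()] or a numeric individuals-by-SNPs matrix.
#' @return A numeric matrix with per-column mean 0 and sample variance 1,
#'   with SNP identifiers as column names and attribute
#'   `standardized = TRUE`.
#' @export
standardize_genotypes <- function(x) {
  if (inherits(x, "genotype_panel")) x <- x$dosages
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (isTRUE(attr(x, "standardized"))) return(x)
  n <- nrow(x)
  if (n < 2) stop("at least two individuals are required")
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr, "-")
  v <- colSums(x^2) / (n - 1)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("monomorphic SNP(s) with zero variance: ",
         paste(bad, collapse = ", "))
  }
  x <- sweep(x, 2, sqrt(v), "/")
  attr(x, "standardized") <- TRUE
  x
}

#' Build a pruned, standardized principal-component projection
#'
#' Computes the singular value decomposition of a standardized genotype
#' matrix and retains the smallest leading set of components whose
#' genotypic-variance shares cumulatively reach `variance_threshold`,
#' pruning the remainder as regularization. Component scores are rescaled so
#' that `t(W) %*% W = (N - 1) * I`, and the loading transform `R` maps
#' standardized dosages onto the scores exactly (`W = X_std %*% R`).
#'
#' @param x_std a standardized genotype matrix from
#'   [standardize_genotypes()] (a [genotype_panel()] is standardized on the
#'   fly).
#' @param variance_threshold cumulative share of genotypic variance to
#'   retain, in `(0, 1]`; 0.99 prunes components jointly explaining the last
#'   1% of variance.
#' @return An object of class `pc_projection`: list with `W` (N x K scores),
#'   `R` (SNPs x K transform), `eigenvalues` (all variance shares), `K`,
#'   `N`, `variance_threshold`, `snp_ids`.
#' @examples
#' p <- simulate_panel(300, 40, seed = 2)
#' proj <- build_projection(standardize_genotypes(p))
#' proj$K
#' @export
build_projection <- function(x_std, variance_threshold = 0.99) {
  if (inherits(x_std, "genotype_panel")) {
    x_std <- standardize_genotypes(x_std)
  }
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    stop("variance_threshold must be in (0, 1]")
  }
  n <- nrow(x_std)
  if (n < 3) stop("at least three individuals are required")
  sv <- svd(x_std)
  d <- sv$d
  pos <- d > max(d) * 1e-10
  if (!any(pos)) stop("genotype matrix has no nonzero singular value")
  shares <- d^2 / sum(d^2)
  cum <- cumsum(shares)
  k <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- sum(pos)
  k <- min(k, sum(pos))
  w <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n - 1)
  r <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(n - 1) / d[seq_len(k)], k)
  structure(
    list(W = w, R = r, eigenvalues = shares, K = k, N = n,
         variance_threshold = variance_threshold,
         snp_ids = colnames(x_std)),
    class = "pc_projection")
}

#' @export
print.pc_projection <- function(x, ...) {
  cat(sprintf(
    "principal-component projection: %d components (of %d SNPs), N = %d\n",
    x$K, length(x$snp_ids), x$N))
  cat(sprintf("  retained variance share: %.4f (threshold %.2f)\n",
              sum(x$eigenvalues[seq_len(x$K)]), x$variance_threshold))
  invisible(x)
}

#' Per-component effect estimates for one trait
#'
#' Container for the estimated principal-component effect vector of a trait
#' together with its (shared) sampling variance. `sigma2 = eta2 / (N - 1)`
#' is the squared standard error of each component effect, with `eta2` the
#' residual trait variance.
#'
#' @param delta numeric length-K effect vector.
#' @param N trait sample size.
#' @param eta2 residual variance estimate.
#' @param trait label, `"expression"` or `"outcome"`.
#' @param snp_ids SNP identifiers of the underlying projection basis, used
#'   to detect basis mismatches between traits.
#' @return An object of class `component_effects`.
#' @export
component_effects <- function(delta, N, eta2, trait = "expression",
                              snp_ids = NULL) {
  delta <- as.numeric(delta)
  k <- length(delta)
  if (k >= N - 1) stop("K must be smaller than N - 1 (residual df exhausted)")
  if (eta2 < 0) stop("eta2 must be nonnegative")
  structure(
    list(delta = delta, sigma2 = eta2 / (N - 1), eta2 = eta2,
         N = as.integer(N), K = k, trait = trait, snp_ids = snp_ids),
    class = "component_effects")
}

#' @export
print.component_effects <- function(x, ...) {
  cat(sprintf("component effects (%s): K = %d, N = %d\n", x$trait, x$K, x$N))
  cat(sprintf("  delta'delta = %.4f, sigma2 = %.3e\n",
              sum(x$delta^2), x$sigma2))
  invisible(x)
}

#' Estimate component effects from a raw trait
#'
#' Reconstructs the multiple regression of a trait on the standardized
#' component scores. Because `t(W) %*% W = (N - 1) * I`, the least-squares
#' coefficients reduce to `delta = t(W) %*% y / (N - 1)`. The trait is
#' centered and scaled to variance 1 first, so that `sum(delta^2)` is the
#' model R-squared and genetic (co)variance estimates are on the
#' heritability scale. The residual variance is estimated with the unbiased
#' least-squares form `eta2 = (N - 1) * (1 - R2) / (N - 1 - K)`.
#'
#' @param proj a [build_projection()] result.
#' @param y numeric trait vector of length `proj$N`.
#' @param trait label passed to [component_effects()].
#' @return A [component_effects()] object.
#' @export
effects_from_trait <- function(proj, y, trait = "expression") {
  stopifnot(inherits(proj, "pc_projection"))
  y <- as.numeric(y)
  if (length(y) != proj$N) stop("trait length must equal the projection N")
  n <- proj$N
  if (proj$K >= n - 1) stop("K must be smaller than N - 1")
  y <- y - mean(y)
  s <- sqrt(sum(y^2) / (n - 1))
  if (s == 0) stop("trait has zero variance")
  y <- y / s
  delta <- drop(crossprod(proj$W, y)) / (n - 1)
  r2 <- sum(delta^2)
  if (r2 > 1 + 1e-8) stop("degenerate fit: R-squared exceeds 1")
  eta2 <- (n - 1) * max(1 - r2, 0) / (n - 1 - proj$K)
  component_effects(delta, N = n, eta2 = eta2, trait = trait,
                    snp_ids = proj$snp_ids)
}

#' Per-SNP marginal association scan
#'
#' Regresses a trait on each SNP separately with simple linear regression on
#' the standardized scale (both SNP and trait scaled to variance 1), so the
#' effect is the SNP-trait sample correlation, i.e. the per-SNP covariance
#' with the standardized trait.
#'
#' @param x a [genotype_panel()] or (standardized) dosage matrix.
#' @param y numeric trait vector.
#' @return A `data.frame` of class `marginal_stats` with columns `snp`,
#'   `a1`, `a2`, `n`, `beta_std`, `se`, `z`.
#' @export
marginal_scan <- function(x, y) {
  x_std <- standardize_genotypes(x)
  y <- as.numeric(y)
  n <- nrow(x_std)
  if (length(y) != n) stop("trait length must match the number of individuals")
  y <- y - mean(y)
  s <- sqrt(sum(y^2) / (n - 1))
  if (s == 0) stop("trait has zero variance")
  y <- y / s
  b <- drop(crossprod(x_std, y)) / (n - 1)
  se <- sqrt(pmax(1 - b^2, 0) / (n - 2))
  z <- ifelse(se > 0, b / se, sign(b) * Inf)
  out <- data.frame(snp = colnames(x_std), a1 = "A", a2 = "B", n = n,
                    beta_std = b, se = se, z = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("marginal_stats", "data.frame")
  out
}

#' Reconstruct component effects from marginal summary statistics
#'
#' Maps standardized per-SNP marginal effects onto the component basis
#' through the projection's loading transform: `delta = t(R) %*% beta_std`.
#' When the summary statistics were computed on the same sample the
#' projection was built from, this reproduces [effects_from_trait()]
#' exactly; with a separate reference panel it is the usual
#' summary-statistics reconstruction.
#'
#' @param proj a [build_projection()] result.
#' @param stats a [marginal_scan()]-style `data.frame` covering exactly the
#'   SNPs of `proj`, in the same order and allele orientation.
#' @param trait label passed to [component_effects()].
#' @return A [component_effects()] object.
#' @export
effects_from_marginal <- function(proj, stats, trait = "expression") {
  stopifnot(inherits(proj, "pc_projection"))
  req <- c("snp", "n", "beta_std")
  if (!all(req %in% names(stats))) {
    stop("stats must have columns snp, n, beta_std")
  }
  if (!identical(as.character(stats$snp), as.character(proj$snp_ids))) {
    stop("SNP set or order mismatch between stats and projection")
  }
  if (length(unique(stats$n)) != 1) {
    stop("sample size N must be constant across SNPs")
  }
  n <- stats$n[1]
  if (proj$K >= n - 1) stop("K must be smaller than N - 1")
  delta <- drop(crossprod(proj$R, stats$beta_std))
  r2 <- sum(delta^2)
  if (r2 > 1 + 1e-8) stop("degenerate fit: R-squared exceeds 1")
  eta2 <- (n - 1) * max(1 - r2, 0) / (n - 1 - proj$K)
  component_effects(delta, N = n, eta2 = eta2, trait = trait,
                    snp_ids = proj$snp_ids)
}

#' Read or write marginal summary statistics
#'
#' Tab-delimited GWAS-summary-statistics dialect with columns
#' `SNP A1 A2 N BETA_STD SE Z`, where `BETA_STD` is on the
#' standardized-covariance scale.
#'
#' @param stats a [marginal_scan()] result.
#' @param file path to a tab-delimited file.
#' @return `read_marginal_stats()` returns a `marginal_stats` data frame;
#'   `write_marginal_stats()` returns `file` invisibly.
#' @export
write_marginal_stats <- function(stats, file) {
  out <- data.frame(SNP = stats$snp, A1 = stats$a1, A2 = stats$a2,
                    N = stats$n, BETA_STD = stats$beta_std, SE = stats$se,
                    Z = stats$z)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_marginal_stats
#' @export
read_marginal_stats <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(snp = as.character(d$SNP), a1 = d$A1, a2 = d$A2,
                    n = d$N, beta_std = d$BETA_STD, se = d$SE, z = d$Z,
                    stringsAsFactors = FALSE)
  class(out) <- c("marginal_stats", "data.frame")
  out
}
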