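#' Define a simulation condition
#'
#' One cell of a simulation grid: gene size, sample sizes, local
#' heritabilities (in percent of trait variance), iteration count, a base
#' seed, and which null is generated. Under the covariance null the true
#' component effect vectors of the two traits are exactly orthogonal, so
#' the true local genetic covariance is zero in every iteration; under the
#' TWAS null the outcome effects are instead orthogonalized against the
#' *estimated* expression effects.
#'
#' @param k_snps SNPs per gene (the block is subset to its first `k_snps`
#'   columns).
#' @param n_expr expression sample size.
#' @param n_out outcome sample size.
#' @param h2_expr local heritability of the expression, percent in
#'   `(0, 100]`.
#' @param h2_out local heritability of the outcome, percent in `[0, 100]`
#'   (0 is allowed only under the TWAS null: the outcome is then pure
#'   noise).
#' @param n_iter number of iterations.
#' @param seed base RNG seed; per-iteration seeds are derived
#'   deterministically from it, the block label and the iteration index.
#' @param null_kind `"covariance"` or `"twas"`.
#' @param variance_threshold cumulative variance share retained by the
#'   component projection.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(k_snps, n_expr, n_out, h2_expr, h2_out,
                          n_iter = 1000, seed = 1,
                          null_kind = c("covariance", "twas"),
                          variance_threshold = 0.99) {
  null_kind <- match.arg(null_kind)
  if (h2_expr <= 0 || h2_expr > 100) {
    stop("h2_expr must be a percentage in (0, 100]")
  }
  if (h2_out < 0 || h2_out > 100) {
    stop("h2_out must be a percentage in [0, 100]")
  }
  if (h2_out == 0 && null_kind != "twas") {
    stop("h2_out = 0 is only defined under the TWAS null")
  }
  structure(
    list(k_snps = as.integer(k_snps), n_expr = as.integer(n_expr),
         n_out = as.integer(n_out), h2_expr = h2_expr, h2_out = h2_out,
         n_iter = as.integer(n_iter), seed = as.integer(seed),
         null_kind = null_kind, variance_threshold = variance_threshold),
    class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "simulation condition (%s null): K_snps = %d, N_E = %d, N_Y = %d\n",
    x$null_kind, x$k_snps, x$n_expr, x$n_out))
  cat(sprintf("  h2_E = %g%%, h2_Y = %g%%, %d iterations, seed %d\n",
              x$h2_expr, x$h2_out, x$n_iter, x$seed))
  invisible(x)
}

cond_hash <- function(cond) {
  mix_seed(cond$k_snps, cond$n_expr, cond$n_out,
           round(cond$h2_expr * 1e4), round(cond$h2_out * 1e4),
           if (cond$null_kind == "twas") 2 else 1)
}

block_hash <- function(block) {
  id <- block$block_id
  if (is.null(id)) id <- "block00"
  mix_seed(utf8ToInt(id))
}

#' Draw exactly orthogonal true effect vectors
#'
#' Draws two independent standard-normal length-K vectors and replaces the
#' second by its residual after regression on the first, so that their
#' inner product is zero to machine precision. Used to generate true
#' component effects under the null of zero local genetic covariance.
#'
#' @param k number of components, at least 2.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return A list with `delta_E` and `delta_Y`, each length `k`, with
#'   `sum(delta_E * delta_Y)` zero to machine precision.
#' @export
draw_orthogonal_effects <- function(k, seed = NULL) {
  if (k < 2) stop("k must be at least 2 (residualization is degenerate)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  d_e <- rnorm(k)
  d_y <- rnorm(k)
  d_y <- d_y - d_e * (sum(d_e * d_y) / sum(d_e^2))
  list(delta_E = d_e, delta_Y = d_y)
}

#' Synthesize a trait with a controlled local heritability
#'
#' Computes the genetic component `G = W %*% delta`, standardizes it to
#' sample variance 1 on the generation sample, and adds independent normal
#' noise with variance `(100 - h2) / h2`, so that the genetic component
#' explains `h2` percent of the trait variance in expectation.
#'
#' @param w component score matrix (rows = individuals of the generation
#'   sample).
#' @param delta nonzero effect vector of length `ncol(w)`.
#' @param h2 local heritability, percent in `(0, 100]`; at 100 the trait is
#'   the standardized genetic component exactly.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return Numeric trait vector of length `nrow(w)`.
#' @export
synthesize_trait <- function(w, delta, h2, seed = NULL) {
  if (h2 <= 0 || h2 > 100) stop("h2 must be a percentage in (0, 100]")
  if (all(delta == 0)) stop("delta must be nonzero; use pure noise for h2 = 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- drop(w %*% delta)
  s <- sd(g)
  if (s == 0) stop("genetic component has zero variance")
  g <- g / s
  if (h2 == 100) return(g)
  g + rnorm(length(g), sd = sqrt((100 - h2) / h2))
}

#' Precompute the per-gene simulation context
#'
#' Builds, once per (block, condition) pair, everything that is shared
#' across iterations: the gene's first `k_snps` SNPs, the pooled analysis
#' sample (the largest of the two nested subsamples), the standardized
#' genotype matrices, and the pruned component projection of the pooled
#' sample. The pooled projection serves both as the basis on which true
#' effects are defined (making the generated null exact) and as the
#' reference panel through which component effects are reconstructed from
#' marginal statistics.
#'
#' @param block a gene-block [genotype_panel()].
#' @param cond a [sim_condition()].
#' @return An object of class `gene_context`.
#' @export
prepare_gene <- function(block, cond) {
  stopifnot(inherits(block, "genotype_panel"),
            inherits(cond, "sim_condition"))
  p <- ncol(block$dosages)
  if (p < cond$k_snps) stop("block has fewer SNPs than k_snps")
  pool_n <- max(cond$n_expr, cond$n_out)
  if (nrow(block$dosages) < pool_n) {
    stop("block has fewer individuals than max(n_expr, n_out)")
  }
  gene <- genotype_panel(block$dosages[, seq_len(cond$k_snps), drop = FALSE],
                         snp_ids = block$snp_ids[seq_len(cond$k_snps)],
                         block_id = block$block_id, seed = block$seed)
  pool <- nested_subsample(gene, pool_n)
  x_pool <- standardize_genotypes(pool)
  proj <- build_projection(x_pool, cond$variance_threshold)
  if (proj$K >= cond$n_expr - 1) {
    stop("retained components reach the expression-sample residual df; ",
         "increase n_expr or reduce k_snps/variance_threshold")
  }
  x_expr <- standardize_genotypes(nested_subsample(gene, cond$n_expr))
  x_out <- if (cond$n_out == pool_n) {
    x_pool
  } else {
    standardize_genotypes(nested_subsample(gene, cond$n_out))
  }
  structure(
    list(block_id = gene$block_id, cond = cond, proj = proj,
         x_expr = x_expr, x_out = x_out,
         w_expr = proj$W[seq_len(cond$n_expr), , drop = FALSE],
         w_out = proj$W[seq_len(cond$n_out), , drop = FALSE]),
    class = "gene_context")
}

new_gene_iteration <- function(delta_E, delta_Y, E, Y, stats_E, stats_Y,
                               seed, null_kind, iter_index,
                               delta_hat_E = NULL) {
  structure(
    list(delta_E_true = delta_E, delta_Y_true = delta_Y, E = E, Y = Y,
         stats_E = stats_E, stats_Y = stats_Y, seed = seed,
         null_kind = null_kind, iter_index = iter_index,
         delta_hat_E = delta_hat_E),
    class = "gene_iteration")
}

#' Simulate one gene iteration under the covariance null
#'
#' Draws exactly orthogonal true component effects on the pooled basis
#' (so `cov(G_E, G_Y) = 0` holds exactly, not just in expectation),
#' synthesizes the expression trait on the first `n_expr` individuals and
#' the outcome on the first `n_out`, and computes per-SNP marginal
#' association scans for both. Fully reproducible from the condition's
#' base seed, the block label and the iteration index.
#'
#' @param block a gene-block [genotype_panel()].
#' @param cond a [sim_condition()] with `null_kind = "covariance"`.
#' @param iter_index iteration number.
#' @param context optional [prepare_gene()] result to reuse across
#'   iterations.
#' @return An object of class `gene_iteration` holding the true effects,
#'   both traits and both marginal scans.
#' @export
simulate_gene_iteration <- function(block, cond, iter_index,
                                    context = NULL) {
  if (is.null(context)) context <- prepare_gene(block, cond)
  seed_used <- mix_seed(cond$seed, cond_hash(cond), block_hash(block),
                        iter_index)
  set.seed(seed_used)
  d <- draw_orthogonal_effects(context$proj$K)
  e <- synthesize_trait(context$w_expr, d$delta_E, cond$h2_expr)
  y <- synthesize_trait(context$w_out, d$delta_Y, cond$h2_out)
  new_gene_iteration(d$delta_E, d$delta_Y, e, y,
                     marginal_scan(context$x_expr, e),
                     marginal_scan(context$x_out, y),
                     seed_used, "covariance", iter_index)
}

#' Simulate one gene iteration under the TWAS null
#'
#' Validation variant: the expression trait is generated first and its
#' component effects are *estimated* from the expression sample's marginal
#' statistics; the outcome's true effects are then drawn orthogonal to
#' those estimates, so `cov(Ghat_E, G_Y) = 0` holds exactly. With
#' `h2_out = 0` the outcome is pure standard-normal noise.
#'
#' @inheritParams simulate_gene_iteration
#' @param cond a [sim_condition()] with `null_kind = "twas"`.
#' @return A `gene_iteration`, with the estimated expression effects in
#'   `$delta_hat_E`.
#' @export
simulate_twas_null_iteration <- function(block, cond, iter_index,
                                         context = NULL) {
  if (is.null(context)) context <- prepare_gene(block, cond)
  k <- context$proj$K
  seed_used <- mix_seed(cond$seed, cond_hash(cond), block_hash(block),
                        iter_index)
  set.seed(seed_used)
  d_e <- rnorm(k)
  e <- synthesize_trait(context$w_expr, d_e, cond$h2_expr)
  stats_e <- marginal_scan(context$x_expr, e)
  hat_e <- effects_from_marginal(context$proj, stats_e,
                                 trait = "expression")
  d_y <- rnorm(k)
  d_y <- d_y - hat_e$delta * (sum(hat_e$delta * d_y) /
                                sum(hat_e$delta^2))
  if (cond$h2_out == 0) {
    y <- rnorm(cond$n_out)
    d_y <- numeric(k)
  } else {
    y <- synthesize_trait(context$w_out, d_y, cond$h2_out)
  }
  new_gene_iteration(d_e, d_y, e, y, stats_e,
                     marginal_scan(context$x_out, y),
                     seed_used, "twas", iter_index, delta_hat_E = hat_e)
}

#' Analyze one simulated gene iteration
#'
#' Runs the full estimation path on a simulated iteration: reconstructs
#' component effects for both traits from their marginal statistics through
#' the shared reference projection, fits [local_cov()], and evaluates the
#' univariate, corrected and conditioned tests and the standard-error
#' deflation.
#'
#' @param iteration a `gene_iteration`.
#' @param context the [prepare_gene()] context it was generated with.
#' @return A list with the fit, the three `cov_test` results, the
#'   deflation, and the p-values as a named vector `p` (elements
#'   `univariate`, `rG`, `TWAS`).
#' @export
analyze_iteration <- function(iteration, context) {
  stopifnot(inherits(iteration, "gene_iteration"),
            inherits(context, "gene_context"))
  expr <- effects_from_marginal(context$proj, iteration$stats_E,
                                trait = "expression")
  outc <- effects_from_marginal(context$proj, iteration$stats_Y,
                                trait = "outcome")
  fit <- local_cov(expr, outc)
  univ <- univariate_test(expr)
  rg <- rg_test(fit)
  tw <- twas_test(fit)
  list(fit = fit, univariate = univ, rg = rg, twas = tw,
       se_deflation = se_deflation(fit),
       p = c(univariate = univ$p, rG = rg$p, TWAS = tw$p))
}
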