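#' Empirical type-1-error rate
#'
#' Proportion of p-values below a threshold, optionally restricted to the
#' iterations passing a univariate filter (as in TWAS practice, where genes
#' without detectable expression signal are excluded before the bivariate
#' test). The Monte-Carlo standard error is the binomial
#' `sqrt(rate * (1 - rate) / n_used)`.
#'
#' @param pvals p-values of the test under evaluation.
#' @param alpha significance threshold in `(0, 1)`.
#' @param filter_pvals optional vector of filter p-values (same length);
#'   only iterations with `filter_pvals < filter_alpha` are kept.
#' @param filter_alpha filter threshold in `(0, 1)`.
#' @return A list with `rate`, `mc_se`, `n_used`. If the filter removes all
#'   iterations, `n_used` is 0 and the rate is `NA`.
#' @examples
#' empirical_type1_error(c(0.01, 0.2, 0.04, 0.8), 0.05)
#' @export
empirical_type1_error <- function(pvals, alpha, filter_pvals = NULL,
                                  filter_alpha = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  keep <- !is.na(pvals)
  if (!is.null(filter_pvals)) {
    if (length(filter_pvals) != length(pvals)) {
      stop("filter_pvals must have the same length as pvals")
    }
    if (is.null(filter_alpha) || filter_alpha <= 0 || filter_alpha >= 1) {
      stop("filter_alpha must be in (0, 1)")
    }
    keep <- keep & !is.na(filter_pvals) & filter_pvals < filter_alpha
  }
  n <- sum(keep)
  if (n == 0) {
    return(list(rate = NA_real_, mc_se = NA_real_, n_used = 0L))
  }
  rate <- mean(pvals[keep] < alpha)
  list(rate = rate, mc_se = sqrt(rate * (1 - rate) / n), n_used = n)
}

#' Type-1-error inflation ratio
#'
#' The observed rejection rate divided by the nominal threshold; equals 1
#' for a calibrated test.
#'
#' @param rate observed type-1-error rate.
#' @param alpha nominal threshold, positive.
#' @return `rate / alpha`.
#' @export
inflation_ratio <- function(rate, alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  rate / alpha
}

#' Run a grid of null simulations
#'
#' For every condition, spreads its iterations evenly over the supplied
#' gene blocks (aggregating results over blocks), simulates each iteration
#' under the condition's null, runs the full estimation and testing path,
#' and tabulates empirical type-1-error rates for the univariate, corrected
#' (rG) and conditioned (TWAS) tests at each requested threshold, plus
#' univariate-filtered variants of the two covariance tests. Iterations
#' that fail (degenerate fits) are recorded with an error status and
#' excluded from the rate denominators, never silently dropped.
#'
#' @param blocks list of gene-block [genotype_panel()] objects.
#' @param conditions list of [sim_condition()] objects (a single condition
#'   is accepted).
#' @param alphas significance thresholds, all in `(0, 1)`.
#' @param filter_alphas univariate-filter thresholds for the filtered
#'   rates; `NULL` disables filtering.
#' @param verbose print per-condition progress.
#' @return An object of class `grid_result`: a list of per-condition
#'   results, each holding the condition, the per-iteration record
#'   `data.frame` (`iter`, `block`, `p_univ`, `p_rG`, `p_TWAS`,
#'   `se_deflation`, `status`) and the long-format `rates` table. Use
#'   [type1_table()] to bind all conditions together.
#' @export
run_grid <- function(blocks, conditions, alphas = 0.05,
                     filter_alphas = NULL, verbose = FALSE) {
  if (inherits(blocks, "genotype_panel")) blocks <- list(blocks)
  if (inherits(conditions, "sim_condition")) conditions <- list(conditions)
  if (!length(blocks) || !length(conditions)) stop("empty blocks or conditions")
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must be in (0, 1)")
  out <- lapply(conditions, function(cond) {
    t0 <- Sys.time()
    n_iter <- cond$n_iter
    nb <- length(blocks)
    per_block <- rep(n_iter %/% nb, nb)
    extra <- n_iter %% nb
    if (extra > 0) per_block[seq_len(extra)] <- per_block[seq_len(extra)] + 1
    rec <- data.frame(iter = seq_len(n_iter), block = NA_character_,
                      p_univ = NA_real_, p_rG = NA_real_,
                      p_TWAS = NA_real_, se_deflation = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    g <- 0L
    sim_fun <- if (cond$null_kind == "twas") {
      simulate_twas_null_iteration
    } else {
      simulate_gene_iteration
    }
    for (b in seq_len(nb)) {
      if (per_block[b] == 0) next
      ctx <- prepare_gene(blocks[[b]], cond)
      for (i in seq_len(per_block[b])) {
        g <- g + 1L
        rec$block[g] <- ctx$block_id
        res <- tryCatch({
          it <- sim_fun(blocks[[b]], cond, g, ctx)
          suppressWarnings(analyze_iteration(it, ctx))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$status[g] <- conditionMessage(res)
        } else {
          rec$p_univ[g] <- res$p[["univariate"]]
          rec$p_rG[g] <- res$p[["rG"]]
          rec$p_TWAS[g] <- res$p[["TWAS"]]
          rec$se_deflation[g] <- res$se_deflation
        }
      }
    }
    rates <- condition_rates(rec, alphas, filter_alphas)
    if (verbose) {
      message(sprintf(
        "condition K=%d N_E=%d N_Y=%d h2_E=%g h2_Y=%g (%s): %d iter, %d failed, %.1fs",
        cond$k_snps, cond$n_expr, cond$n_out, cond$h2_expr, cond$h2_out,
        cond$null_kind, n_iter, sum(rec$status != "ok"),
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    structure(list(condition = cond, iterations = rec, rates = rates,
                   n_failed = sum(rec$status != "ok")),
              class = "condition_result")
  })
  structure(out, class = "grid_result")
}

condition_rates <- function(rec, alphas, filter_alphas) {
  methods <- c(univariate = "p_univ", rG = "p_rG", TWAS = "p_TWAS")
  rows <- list()
  for (m in names(methods)) {
    p <- rec[[methods[[m]]]]
    for (a in alphas) {
      r <- empirical_type1_error(p, a)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, alpha = a, filter = NA_real_, rate = r$rate,
        mc_se = r$mc_se, n_used = r$n_used, stringsAsFactors = FALSE)
      if (m != "univariate" && !is.null(filter_alphas)) {
        for (fa in filter_alphas) {
          rf <- empirical_type1_error(p, a, rec$p_univ, fa)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, alpha = a, filter = fa, rate = rf$rate,
            mc_se = rf$mc_se, n_used = rf$n_used, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("simulation grid: %d condition(s)\n", length(x)))
  print(type1_table(x))
  invisible(x)
}

#' Long-format type-1-error table for a grid run
#'
#' Binds the per-condition rate tables of a [run_grid()] result into one
#' long-format `data.frame` with the condition parameters as columns.
#'
#' @param results a `grid_result`.
#' @return A `data.frame` with columns `k_snps`, `n_expr`, `n_out`,
#'   `h2_expr`, `h2_out`, `null_kind`, `method`, `alpha`, `filter`,
#'   `rate`, `mc_se`, `n_used`.
#' @export
type1_table <- function(results) {
  stopifnot(inherits(results, "grid_result"))
  do.call(rbind, lapply(results, function(cr) {
    cond <- cr$condition
    cbind(data.frame(k_snps = cond$k_snps, n_expr = cond$n_expr,
                     n_out = cond$n_out, h2_expr = cond$h2_expr,
                     h2_out = cond$h2_out, null_kind = cond$null_kind,
                     stringsAsFactors = FALSE),
          cr$rates, row.names = NULL)
  }))
}
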