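# build a matched expression/outcome pair on one shared basis
paired_fit_fixture <- function(n_e = 300, n_y = 800, p = 12, h2_e = 20,
                               h2_y = 5, seed = 77, orthogonal = TRUE) {
  panel <- simulate_panel(n_y, p, ld_decay = 0.5, seed = seed)
  x_pool <- standardize_genotypes(panel)
  proj <- build_projection(x_pool, 1.0)
  set.seed(seed + 1)
  if (orthogonal) {
    d <- draw_orthogonal_effects(proj$K)
  } else {
    d <- list(delta_E = rnorm(proj$K), delta_Y = rnorm(proj$K))
  }
  e <- synthesize_trait(proj$W[seq_len(n_e), , drop = FALSE], d$delta_E, h2_e)
  y <- synthesize_trait(proj$W, d$delta_Y, h2_y)
  x_e <- standardize_genotypes(nested_subsample(panel, n_e))
  expr <- effects_from_marginal(proj, marginal_scan(x_e, e))
  outc <- effects_from_marginal(proj, marginal_scan(x_pool, y),
                                trait = "outcome")
  list(proj = proj, fit = local_cov(expr, outc), expr = expr, outc = outc,
       e = e, y = y, d = d, panel = panel)
}

test_that("the univariate F-test matches a textbook multiple regression", {
  panel <- simulate_panel(300, 8, ld_decay = 0.4, seed = 15)
  x <- standardize_genotypes(panel)
  proj <- build_projection(x, 1.0)
  set.seed(16)
  y <- synthesize_trait(proj$W, rnorm(proj$K), 10)
  eff <- effects_from_trait(proj, y)
  got <- univariate_test(eff)
  # oracle: residual-sum-of-squares F from lm on the component scores
  ref <- summary(lm(scale(y) ~ proj$W))$fstatistic
  expect_equal(got$z_or_F, unname(ref["value"]), tolerance = 1e-6)
  expect_equal(got$dof, unname(ref[c("numdf", "dendf")]))

  # zero effects give F = 0, p = 1
  null_eff <- component_effects(rep(0, 5), N = 100, eta2 = 1)
  z <- univariate_test(null_eff)
  expect_equal(z$z_or_F, 0)
  expect_equal(z$p, 1)
})

test_that("the univariate test is calibrated under pure-noise traits", {
  panel <- simulate_panel(120, 10, ld_decay = 0.3, seed = 18)
  proj <- build_projection(standardize_genotypes(panel), 1.0)
  set.seed(19)
  reps <- 2000
  pv <- replicate(reps, {
    univariate_test(effects_from_trait(proj, rnorm(proj$N)))$p
  })
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("method-of-moments covariance entries follow their definitions", {
  e <- component_effects(c(0.3), N = 100, eta2 = 0.9)
  y <- component_effects(c(0.2), N = 1000, eta2 = 1, trait = "outcome")
  fit <- local_cov(e, y)
  expect_equal(fit$omega_EY, 0.06)
  expect_equal(fit$omega_E2, 0.09 - 1 * 0.9 / 99)
  expect_equal(unname(coef(fit)["omega_Y2"]), 0.04 - 1 / 999)

  # all-zero effects leave only the (negative) noise correction
  z <- component_effects(rep(0, 4), N = 50, eta2 = 1)
  z2 <- component_effects(rep(0, 4), N = 60, eta2 = 1, trait = "outcome")
  fz <- local_cov(z, z2)
  expect_equal(fz$omega_EY, 0)
  expect_equal(fz$omega_E2, -4 / 49)

  # mismatched bases are rejected
  a <- component_effects(rnorm(3), N = 50, eta2 = 1, snp_ids = c("a", "b", "c"))
  b <- component_effects(rnorm(3), N = 50, eta2 = 1, snp_ids = c("a", "b", "d"))
  expect_error(local_cov(a, b), "mismatch")
  expect_error(local_cov(component_effects(rnorm(2), 50, 1), a), "mismatch")
})

test_that("omega_E2 is an unbiased estimate of the true effect mass", {
  set.seed(101)
  k <- 10
  delta <- rnorm(k, sd = 0.2)
  sigma2 <- 0.01
  reps <- 10000
  est <- replicate(reps, {
    dh <- delta + rnorm(k, sd = sqrt(sigma2))
    sum(dh^2) - k * sigma2
  })
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - sum(delta^2)), 3 * mc_se)
})

test_that("the corrected test's plug-in variance matches Monte-Carlo truth", {
  set.seed(55)
  k <- 50
  delta_e <- rnorm(k, sd = sqrt(0.05 / k))
  delta_y <- rnorm(k, sd = sqrt(0.01 / k))
  delta_y <- delta_y - delta_e * sum(delta_e * delta_y) / sum(delta_e^2)
  s_e <- 2e-3
  s_y <- 1e-4
  reps <- 5000
  om <- replicate(reps, {
    de <- delta_e + rnorm(k, sd = sqrt(s_e))
    dy <- delta_y + rnorm(k, sd = sqrt(s_y))
    sum(de * dy)
  })
  v_true <- k * s_e * s_y + sum(delta_e^2) * s_y + sum(delta_y^2) * s_e
  expect_lt(abs(var(om) / v_true - 1), 0.10)

  # a zero covariance estimate gives z = 0, p = 1
  e0 <- component_effects(c(rep(0.1, 25), rep(-0.1, 25)), N = 500, eta2 = 1)
  y0 <- component_effects(rep(0.1, 50), N = 500, eta2 = 1,
                          trait = "outcome")
  f0 <- local_cov(e0, y0)
  expect_equal(f0$omega_EY, 0, tolerance = 1e-12)
  r0 <- rg_test(f0)
  expect_equal(r0$z_or_F, 0)
  expect_equal(r0$p, 1)
})

test_that("the conditioned test equals a direct regression on predicted expression", {
  fx <- paired_fit_fixture(n_e = 400, n_y = 500, p = 20, seed = 88,
                           orthogonal = FALSE)
  tw <- suppressWarnings(twas_test(fx$fit))
  # oracle: least-squares regression of the outcome on Ghat_E = W delta_hat_E
  ghat <- drop(fx$proj$W %*% fx$expr$delta)
  ys <- drop(scale(fx$y))
  co <- summary(lm(ys ~ ghat))$coefficients
  z_ref <- co["ghat", "t value"]
  expect_equal(tw$z_or_F, unname(z_ref), tolerance = 0.05)
})

test_that("both covariance tests share the statistic and order their p-values", {
  fx <- paired_fit_fixture(seed = 91)
  rg <- suppressWarnings(rg_test(fx$fit))
  tw <- suppressWarnings(twas_test(fx$fit))
  expect_identical(rg$statistic, tw$statistic)
  expect_lte(tw$p, rg$p)
  cmp <- suppressWarnings(compare_tests(fx$fit))
  expect_equal(cmp$p_TWAS, tw$p)
  expect_equal(cmp$p_rG, rg$p)
  # strict ordering whenever the truncated outcome genetic variance is positive
  if (fx$fit$omega_Y2 > 0) expect_lt(cmp$p_TWAS, cmp$p_rG)
})

test_that("variance decomposition and deflation identities hold", {
  fx <- paired_fit_fixture(seed = 93)
  fit <- fx$fit
  rg <- suppressWarnings(rg_test(fit))
  tw <- suppressWarnings(twas_test(fit))
  defl <- se_deflation(fit)
  # V_TWAS + sigma2_E * omega_Y2(+) = V_rG when omega_E2 >= 0
  expect_gt(fit$omega_E2, 0)
  expect_equal(tw$se^2 + fit$sigma2_E * max(fit$omega_Y2, 0), rg$se^2,
               tolerance = 1e-12)
  expect_equal(defl, tw$se / rg$se, tolerance = 1e-12)
  expect_true(defl > 0 && defl <= 1)
  # the z-ratio identity: deflating the corrected p reproduces the TWAS p
  expect_equal(biased_pvalue(rg$p, defl), tw$p, tolerance = 1e-10)
})

test_that("deflation is 1 without outcome signal and decreases in omega_Y2", {
  e <- component_effects(rnorm(40, sd = 0.1), N = 500, eta2 = 0.9)
  base <- component_effects(rep(0, 40), N = 5000, eta2 = 1, trait = "outcome")
  f0 <- local_cov(e, base)
  expect_lt(f0$omega_Y2, 0)  # pure noise: raw estimate is negative
  expect_equal(se_deflation(f0), 1)
  p0 <- suppressWarnings(compare_tests(f0))
  expect_equal(p0$p_TWAS, p0$p_rG)

  # increasing outcome genetic variance monotonically lowers the deflation
  defl <- sapply(c(0.001, 0.01, 0.05), function(w2) {
    oy <- component_effects(rep(sqrt(w2 / 40 + 1 / 4999), 40), N = 5000,
                            eta2 = 1, trait = "outcome")
    se_deflation(local_cov(e, oy))
  })
  expect_true(all(diff(defl) < 0))
})

test_that("estimation error in the expression effects carries the predicted variance", {
  # decomposition diagnostic: delta_hat_E' delta_Y = delta_E' delta_Y +
  # (delta_hat_E - delta_E)' delta_Y, and the second term has variance
  # sigma2_E * omega_Y2
  set.seed(120)
  k <- 40
  delta_y <- rnorm(k, sd = sqrt(0.02 / k))
  delta_e <- rnorm(k, sd = sqrt(0.05 / k))
  s_e <- 1.5e-3
  reps <- 6000
  chat <- replicate(reps, {
    dh <- delta_e + rnorm(k, sd = sqrt(s_e))
    sum((dh - delta_e) * delta_y)
  })
  expect_equal(mean(chat), 0, tolerance = 4 * sd(chat) / sqrt(reps))
  v_pred <- s_e * sum(delta_y^2)
  expect_lt(abs(var(chat) / v_pred - 1), 0.10)
})

test_that("summary and print methods expose the per-gene results row", {
  fx <- paired_fit_fixture(seed = 95)
  s <- suppressWarnings(summary(fx$fit))
  row <- as.data.frame(s, gene = "g1")
  expect_identical(names(row),
                   c("gene", "K", "N_E", "N_Y", "omega_E2", "omega_Y2",
                     "omega_EY", "p_univ_E", "p_rG", "p_TWAS",
                     "se_deflation"))
  expect_equal(row$p_rG, s$rg$p)
  expect_output(print(s), "deflation")
  expect_output(print(fx$fit), "omega_EY")
})

test_that("degenerate inputs are rejected by the tests", {
  e <- component_effects(rep(0, 40), N = 500, eta2 = 1)
  y <- component_effects(rnorm(40, sd = 0.05), N = 1000, eta2 = 1,
                         trait = "outcome")
  fit <- local_cov(e, y)
  expect_error(twas_test(fit), "zero variance")
  expect_error(se_deflation(fit), "zero variance")
  small <- local_cov(component_effects(rnorm(5), N = 100, eta2 = 1),
                     component_effects(rnorm(5), N = 100, eta2 = 1,
                                       trait = "outcome"))
  expect_warning(rg_test(small), "K < 30")
})
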