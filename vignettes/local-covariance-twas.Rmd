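---
title: "Testing local genetic covariance versus the conditioned TWAS test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing local genetic covariance versus the conditioned TWAS test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localcov)
```

## The model

A TWAS-style analysis works with the SNPs `X` local to one gene. Two traits
are partitioned against that genotype matrix: gene expression
`E = X alpha_E + xi_E` and an outcome phenotype `Y = X alpha_Y + xi_Y`,
with `G_E = X alpha_E` and `G_Y = X alpha_Y` the local genetic components.
A genetic relationship between expression and outcome within the region
means `cov(G_E, G_Y) != 0`.

Because local SNPs are highly collinear and usually outnumber the
expression sample, `localcov` regularizes by projecting the standardized
genotypes onto pruned principal components, `W = X_std R`, rescaled so that
`t(W) %*% W = (N - 1) * I_K`. Components are retained in order of
eigenvalue until they jointly explain a set share of the genotypic
variance (99% by default); ties are broken by original component order.
On this basis `G_E = W delta_E` and `G_Y = W delta_Y`, and the per-trait
effect estimates are exact multiple-regression coefficients:

```
delta_hat = t(W) %*% y / (N - 1),    delta_hat ~ MVN(delta, sigma2 * I_K),
sigma2 = eta2 / (N - 1),
```

with `eta2` the residual trait variance. When only marginal (per-SNP)
summary statistics are available, the same vector is reconstructed through
the loading transform, `delta_hat = t(R) %*% beta_std`; on the sample the
projection was built from the two routes coincide exactly, and the package
tests that identity to 1e-8.

The local genetic covariance matrix is estimated by the method of moments,
subtracting the known sampling-noise mass from the raw cross-products:

```
Omega_hat = t(delta_hat) %*% delta_hat - K * Sigma_hat
```

With no sample overlap between the expression and outcome cohorts (the
only case implemented), the sampling covariance between traits is zero and
the covariance estimate is simply `omega_EY = sum(delta_E * delta_Y)`. The
diagonal entries `omega_E2`, `omega_Y2` may come out negative in finite
samples; they are stored raw for diagnostics and truncated at zero only
where a variance is mathematically required.

## The two tests and the deflation that links them

Both tests use the identical statistic `omega_EY`; the package's central
design point is that they differ in nothing but the null variance.

* The **corrected test** (`rg_test()`) evaluates
  `H0: cov(G_E, G_Y) = 0` with
  `V_rG = K*s2_E*s2_Y + omega_E2*s2_Y + s2_E*omega_Y2`,
  accounting for sampling of both traits. The statistic is a sum of K
  product-normal terms; its null distribution is approximated by a normal,
  which is accurate for moderate K (the package warns below K = 30). A
  two-sided p-value is reported.
* The **conditioned test** (`twas_test()`) evaluates
  `H0: cov(Ghat_E, G_Y) = 0`, treating the predicted expression component
  `Ghat_E = W %*% delta_hat_E` as fixed, exactly as the second stage of a
  two-stage TWAS does. Conditionally on `delta_hat_E`, the null variance
  reduces to `V_TWAS = sum(delta_hat_E^2) * s2_Y`. This equals the z-test
  of a direct regression of the outcome on `Ghat_E`, an identity the test
  suite checks against `lm()`.

Since `sum(delta_hat_E^2) = omega_E2 + K*s2_E`, the two variances obey
`V_rG = V_TWAS + s2_E * omega_Y2` exactly, so the conditioned test's
standard error is deflated by

```
se_deflation = sqrt(V_TWAS / (V_TWAS + s2_E * max(omega_Y2, 0))) <= 1 ,
```

with equality exactly when the outcome carries no local genetic variance.
`biased_pvalue()` converts any reference p-value through this z-ratio
(`z / deflation`), and `biased_pvalue(p_rG, se_deflation)` reproduces
`p_TWAS` per gene — the analytic face of the same identity. At the
deflation 0.89 used as a running example, a reference p of 0.05 becomes
0.028 (1.8-fold), and 1e-4 becomes 1.2e-5 (8.1-fold): the relative bias
grows as the reference p-value shrinks, which is why multiple-testing
regimes are hit hardest.

## What the synthetic generator emulates

`simulate_panel()` stands in for a large biobank genotype panel of
unrelated individuals. Each haplotype is a latent Gaussian AR(1) chain
across SNP positions (lag-1 correlation `ld_decay`, default 0.95),
thresholded per SNP at the normal quantile of a target allele frequency
drawn uniformly from `maf_range` (default 0.05–0.5). This yields exact
Hardy–Weinberg dosages with LD that decays monotonically with distance,
and an adjacent-SNP dosage correlation around 0.65, typical of dense
panels. MAF filtering at 5% on the full pool plus nested (prefix)
subsampling guarantees every SNP keeps a minor allele at every sample
size; gene blocks are consecutive SNP windows spread evenly across the
panel, subset to their first K SNPs for smaller gene sizes.

Trait generation follows the grid conventions of TWAS-null simulation
studies: local heritabilities are specified in percent; the genetic
component `W %*% delta` is standardized to variance 1 on the generation
sample and noise with variance `(100 - h2)/h2` is added, so the realized
variance explained matches `h2` up to sampling error (a calibration the
tests verify). Two nulls are available:

* **covariance null** — `delta_E` and `delta_Y` are drawn standard normal
  and `delta_Y` is residualized on `delta_E`, making the true local
  genetic covariance exactly zero in every iteration, not just in
  expectation.
* **TWAS null** — the expression trait is generated first, its component
  effects are *estimated* from the expression sample's marginal scan, and
  `delta_Y` is drawn orthogonal to those estimates (with `h2_Y = 0`
  allowed: the outcome is then pure noise). This is the regime in which
  the conditioned test is the correct test, and it is where its
  calibration is validated.

One projection per (block, condition) is built from the pooled (largest)
analysis sample and plays two roles: truth basis (orthogonality of the
true effect vectors then implies a zero covariance of the genetic
components in the pooled sample) and reference panel for reconstructing
`delta_hat` from each cohort's marginal statistics. A per-trait basis is
not an option — the cross-product `delta_E' delta_Y` is only meaningful on
a shared basis — and the shared-reference construction mirrors how
summary-statistics analyses use an external LD panel. Per-iteration seeds
are mixed deterministically from the base seed, the block label and the
iteration index, so grids are reproducible and block-parallel safe.

What the generator does **not** emulate: real haplotype-block LD with
near-duplicate SNPs. Under the thresholded copula with independently drawn
allele frequencies, inter-SNP dosage correlation is capped well below 1,
so the 99%-variance rank of a block stays high (roughly 90 of 100 SNPs,
220 of 250) where real genotype blocks compress far more. Since the noise
mass `K * s2_E` in `V_TWAS` grows with the retained rank, this makes the
conditioned test's inflation *milder* in our simulations than in matched
real-data conditions at small outcome heritability; at `N_Y = 10,000` and
`h2_Y = 0.1%` the expected rejection rate at `alpha = 0.05` is only about
0.055–0.06. The strong qualitative patterns — inflation growing with
`h2_Y` and `N_Y`, and growing with stricter thresholds — are robust to
this and are what the test suite asserts. Passing tests therefore show
correctness of the machinery and the direction and approximate magnitude
of the effect, not a quantitative match to any real cohort.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `ld_decay` | lag-1 latent haplotype correlation | 0.95 | adjacent dosage correlation ~0.65, dense-panel-like |
| `maf_range` | target allele-frequency interval | (0.05, 0.5) | common variants; matches the 5% MAF filter |
| `variance_threshold` | PC variance share retained | 0.99 | prunes only near-redundant components |
| `h2_expr`, `h2_out` | local heritabilities (percent) | per grid | typical eQTL signal is 1–10%; outcome loci 0.001–1% |
| `filter_alphas` | univariate filter thresholds | 0.05, 0.001, 1e-4 | common TWAS gene-filtering practice |

## Numerical choices and degenerate inputs

* Traits are standardized to variance 1 before estimation, so
  `sum(delta^2)` is the model R-squared and the omega quantities sit on
  the heritability scale. Whether the reference implementation of the
  local-correlation framework rescales traits is not documented; this is
  our convention, and it only changes units, not z-statistics.
* The residual variance uses the unbiased least-squares form
  `eta2 = (N-1)(1-R2)/(N-1-K)`, matching the univariate F-test's degrees
  of freedom; `K >= N - 1` is refused (no residual df), and the simulator
  refuses conditions whose retained rank reaches the expression sample's
  df.
* Negative `omega^2` estimates are truncated at zero inside `V_rG` and in
  the deflation denominator only; raw values stay in the fit object.
* Monomorphic SNPs are an error (named), missing dosages are mean-imputed
  before scaling, and marginal/projection SNP sets must match exactly in
  order — no allele flipping is attempted.
* The grid runner records failed iterations with a status string and
  excludes them from rate denominators rather than dropping them
  silently; `empirical_type1_error()` flags an all-filtered cell with
  `n_used = 0` instead of returning a number.
* Quantiles of deflation distributions use type-7 linear interpolation.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run two gene blocks per panel
and 2000 iterations per condition: calibration is checked at
`K_snps = 100, N_E = 500, N_Y = 5000, h2_E = 5%, h2_Y = 0.1%`, and the
inflation properties at `K_snps = 250, N_E = 1000, N_Y = 10,000` across
`h2_Y` in {0.001, 0.01, 0.1, 1}%. These sizes give binomial Monte-Carlo
standard errors of about 0.005 on a rate of 0.05, small enough to resolve
the effects of interest while keeping a full run in the minutes range.
`N_E = 1000` is used for the inflation grid because the larger gene size
(250 SNPs) needs the expression-sample residual df, and it matches the
convention of varying gene size at the larger expression cohort.

## Known limitations

* No sample overlap between cohorts (the sampling covariance off-diagonal
  is fixed at zero); no binary traits, covariates, or trans effects.
* The corrected test uses the normal approximation to the product-normal
  sum; below ~30 components it warns rather than switching to an exact
  sampling scheme.
* Local genetic *correlation* point estimates and confidence intervals are
  out of scope; only the covariance tests are provided.
* The LD generator's rank compression is weaker than real genotype data,
  as discussed above; absolute inflation at small `h2_Y` and moderate
  `N_Y` should be read with that in mind.
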