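# small shared fixtures, built in code

# deterministic small panel for structural tests
tiny_panel <- function(n = 200, p = 30, seed = 42, ld = 0.8) {
  simulate_panel(n, p, ld_decay = ld, seed = seed)
}

# panel + projection + a trait with known heritability, for estimation tests
sim_gene_fixture <- function(n = 300, p = 12, h2 = 30, seed = 5) {
  panel <- simulate_panel(n, p, ld_decay = 0.5, seed = seed)
  x <- standardize_genotypes(panel)
  proj <- build_projection(x, 1.0)
  set.seed(seed + 1)
  delta <- rnorm(proj$K)
  y <- synthesize_trait(proj$W, delta, h2)
  list(panel = panel, x = x, proj = proj, delta = delta, y = y)
}

# hand-built dosage matrix with exact target MAFs
panel_with_mafs <- function(mafs, n = 50) {
  dos <- sapply(mafs, function(q) {
    cnt <- round(2 * n * q)
    d <- integer(n)
    d[seq_len(cnt %/% 2)] <- 2L
    if (cnt %% 2 == 1) d[cnt %/% 2 + 1] <- 1L
    d
  })
  genotype_panel(dos)
}
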