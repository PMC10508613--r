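#' Construct a genotype panel
#'
#' A genotype panel holds an individuals-by-SNPs matrix of integer allele
#' dosages (0/1/2), per-SNP minor allele frequencies recomputed from the
#' dosages, and an optional gene-block label. It stands in for a reference
#' cohort of unrelated individuals, such as a biobank genotype panel.
#'
#' @param dosages integer matrix (individuals x SNPs) with values in
#'   \{0, 1, 2\}. `NA` entries are allowed and are mean-imputed downstream by
#'   [standardize_genotypes()].
#' @param snp_ids character vector of SNP identifiers; defaults to the column
#'   names of `dosages` or `snp0001`-style labels.
#' @param block_id optional single label naming the gene block this panel
#'   represents.
#' @param seed RNG seed the panel was generated with, if any (bookkeeping
#'   only).
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `maf`, `snp_ids`, `block_id`, `seed`.
#' @export
genotype_panel <- function(dosages, snp_ids = NULL, block_id = NULL,
                           seed = NA_integer_) {
  dosages <- as.matrix(dosages)
  ok <- is.na(dosages) | dosages == 0 | dosages == 1 | dosages == 2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) {
    snp_ids <- sprintf("snp%04d", seq_len(ncol(dosages)))
  }
  if (length(snp_ids) != ncol(dosages)) {
    stop("snp_ids length must match the number of SNP columns")
  }
  colnames(dosages) <- snp_ids
  structure(
    list(dosages = dosages, maf = .panel_maf(dosages),
         snp_ids = as.character(snp_ids), block_id = block_id, seed = seed),
    class = "genotype_panel")
}

# folded allele frequency from dosage columns (NA-tolerant)
.panel_maf <- function(dosages) {
  q <- colMeans(dosages, na.rm = TRUE) / 2
  unname(pmin(q, 1 - q))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (!is.null(x$block_id)) cat("  block:", x$block_id, "\n")
  cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' Simulate a genotype panel with autoregressive linkage disequilibrium
#'
#' Generates biallelic dosages from a latent-Gaussian AR(1) copula: each of
#' the two haplotypes of an individual is an AR(1) Gaussian chain across SNP
#' positions with lag-1 correlation `ld_decay`, thresholded per SNP at the
#' normal quantile of its target allele frequency. Alleles are therefore
#' Bernoulli at the target frequency, dosages follow Hardy-Weinberg
#' proportions, and correlation between SNPs decays monotonically with
#' column distance.
#'
#' @param n_individuals number of individuals (rows), at least 2.
#' @param n_snps number of SNPs (columns).
#' @param ld_decay lag-1 correlation of the latent haplotype chains, in
#'   `[0, 1)`. 0 gives independent SNPs.
#' @param maf_range length-2 interval within `(0, 0.5]` from which target
#'   allele frequencies are drawn uniformly.
#' @param seed integer RNG seed; the panel is fully reproducible from it.
#' @param return_latent if `TRUE`, attach the two latent haplotype matrices
#'   as the `"latent"` attribute (used for LD diagnostics).
#' @return A [genotype_panel()].
#' @examples
#' p <- simulate_panel(200, 50, ld_decay = 0.9, seed = 1)
#' range(p$maf)
#' @export
simulate_panel <- function(n_individuals, n_snps, ld_decay = 0.95,
                           maf_range = c(0.05, 0.5), seed,
                           return_latent = FALSE) {
  if (n_individuals < 2) stop("n_individuals must be at least 2")
  if (n_snps < 1) stop("n_snps must be positive")
  if (!is.numeric(ld_decay) || length(ld_decay) != 1 ||
      ld_decay < 0 || ld_decay >= 1) {
    stop("ld_decay must be a single value in [0, 1)")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  q <- runif(n_snps, maf_range[1], maf_range[2])
  thr <- qnorm(q)
  hap <- function() {
    z <- matrix(rnorm(n_individuals * n_snps), n_individuals, n_snps)
    if (ld_decay > 0 && n_snps > 1) {
      s <- sqrt(1 - ld_decay^2)
      for (j in 2:n_snps) z[, j] <- ld_decay * z[, j - 1] + s * z[, j]
    }
    z
  }
  h1 <- hap()
  h2 <- hap()
  dos <- (sweep(h1, 2, thr, "<")) + (sweep(h2, 2, thr, "<"))
  panel <- genotype_panel(dos, seed = as.integer(seed))
  if (return_latent) attr(panel, "latent") <- list(h1 = h1, h2 = h2)
  panel
}

#' Filter SNPs on minor allele frequency
#'
#' Recomputes the MAF on the first `reference_n` individuals and removes all
#' SNPs with MAF strictly below `threshold`, preserving column order. Using
#' the full panel as the reference (the default) together with nested
#' subsampling guarantees a sufficient minor-allele count at every nested
#' sample size.
#'
#' @param panel a [genotype_panel()].
#' @param threshold MAF cutoff in `[0, 0.5]`; SNPs with MAF < threshold are
#'   dropped.
#' @param reference_n number of leading individuals on which the MAF is
#'   computed; defaults to all individuals.
#' @return The filtered [genotype_panel()].
#' @export
filter_maf <- function(panel, threshold = 0.05, reference_n = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  n <- nrow(panel$dosages)
  if (is.null(reference_n)) reference_n <- n
  if (reference_n > n) stop("reference_n exceeds the number of individuals")
  maf_ref <- .panel_maf(panel$dosages[seq_len(reference_n), , drop = FALSE])
  keep <- maf_ref >= threshold
  if (!any(keep)) stop("all SNPs removed by the MAF filter")
  genotype_panel(panel$dosages[, keep, drop = FALSE],
                 snp_ids = panel$snp_ids[keep],
                 block_id = panel$block_id, seed = panel$seed)
}

#' Split a panel into evenly spaced gene blocks
#'
#' Selects `n_blocks` disjoint blocks of `block_size` consecutive SNPs,
#' spread evenly across the column range, each representing one simulated
#' gene. Subsetting a block to its first K SNPs yields the smaller gene
#' sizes of a simulation grid.
#'
#' @param panel a [genotype_panel()].
#' @param n_blocks number of blocks.
#' @param block_size SNPs per block; `n_blocks * block_size` must not exceed
#'   the number of SNPs.
#' @return A list of [genotype_panel()] objects with `block_id` labels.
#' @export
select_gene_blocks <- function(panel, n_blocks, block_size) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- ncol(panel$dosages)
  if (n_blocks < 1 || block_size < 1) stop("n_blocks and block_size must be positive")
  if (n_blocks * block_size > p) {
    stop("insufficient SNPs: n_blocks * block_size exceeds the panel width")
  }
  stride <- p %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * stride + 1L
  lapply(seq_len(n_blocks), function(b) {
    idx <- starts[b]:(starts[b] + block_size - 1L)
    genotype_panel(panel$dosages[, idx, drop = FALSE],
                   snp_ids = panel$snp_ids[idx],
                   block_id = sprintf("block%02d", b), seed = panel$seed)
  })
}

#' Take a nested subsample of individuals
#'
#' Returns the first `n` rows of the panel, so that subsamples of different
#' sizes are nested: the rows of `nested_subsample(p, a)` are a prefix of
#' those of `nested_subsample(p, b)` whenever `a <= b`.
#'
#' @param panel a [genotype_panel()].
#' @param n number of individuals to keep.
#' @return A [genotype_panel()] with `n` rows.
#' @export
nested_subsample <- function(panel, n) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n > nrow(panel$dosages)) stop("n exceeds the number of individuals")
  if (n < 1) stop("n must be positive")
  genotype_panel(panel$dosages[seq_len(n), , drop = FALSE],
                 snp_ids = panel$snp_ids, block_id = panel$block_id,
                 seed = panel$seed)
}

#' Read or write a plain-text genotype matrix
#'
#' Tab-delimited individuals-by-SNPs dosage matrix with a header row of SNP
#' identifiers. This is the package's external genotype interface; VCF import
#' is out of scope.
#'
#' @param panel a [genotype_panel()].
#' @param file path to a tab-delimited file.
#' @return `read_panel()` returns a [genotype_panel()]; `write_panel()`
#'   returns `file` invisibly.
#' @export
write_panel <- function(panel, file) {
  stopifnot(inherits(panel, "genotype_panel"))
  utils::write.table(panel$dosages, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE)
  genotype_panel(as.matrix(d), snp_ids = colnames(d))
}

# deterministic small-integer seed mixer, kept below 2^31 - 1
mix_seed <- function(...) {
  v <- c(...)
  v <- v[!is.na(v)]
  h <- 0
  for (x in as.numeric(v)) {
    h <- (h * 69069 + abs(x) %% 2147483647) %% 2147483647
  }
  as.integer(h)
}
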