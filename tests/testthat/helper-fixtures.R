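# Shared fixture builders. Everything is generated in code; no stored data.

# tiny geno_matrix from a bare dosage matrix
gm_from <- function(dosage, type = NULL, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  v <- data.frame(
    variant_id = sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% (1000L * seq_len(m)),
    type = type %||% rep("SNP", m),
    ref = "A", alt = "C", stringsAsFactors = FALSE)
  v$alt[v$type == "INDEL"] <- "AC"
  geno_matrix(dosage, v)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# standard small simulated dataset used across tests
sim_dataset <- function(n = 300, n_snp = 1000, n_indel = 100, h2_snp = 0.3,
                        h2_indel = 0, n_causal_snp = NULL, n_causal_indel = 0,
                        fst = 0.1, rho = 0.7, block = 20, missing = 0,
                        seed = 1) {
  if (is.null(n_causal_snp))
    n_causal_snp <- if (h2_snp > 0) max(5L, min(100L, n_snp %/% 5L)) else 0L
  # small cohorts get fewer batch levels so the fixed-effect design stays
  # full rank under random assignment
  fx <- list(farm = c(0, 2, -1, 3), sex = c(0, 0.5),
             batch = if (n >= 500) round(seq(-0.6, 0.6, length.out = 13), 3)
                     else seq(-0.4, 0.4, length.out = 4))
  sim <- simulate_genotypes(sim_config(
    n_individuals = n, n_snp = n_snp, n_indel = n_indel, fst = fst,
    block_size = block, within_block_corr = rho, missing_rate = missing,
    seed = seed))
  ph <- simulate_phenotypes(sim$gm, trait_config(
    h2_snp = h2_snp, h2_indel = h2_indel, n_causal_snp = n_causal_snp,
    n_causal_indel = n_causal_indel, fixed_effects = fx,
    seed = seed + 1000L))
  list(gm = sim$gm, panel = sim$panel, pheno = ph$pheno, truth = ph$truth)
}

# named corrected phenotype shortcut (fixed effects only, fast)
yc_of <- function(ds) adjust_phenotypes(ds$pheno, "trait", method = "fixed_only")

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
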