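#' Configuration for the synthetic genotype generator
#'
#' The generator emulates the statistical structure of a crossbred commercial
#' pig population descended from a small number of sire lines: several
#' admixed subpopulations whose allele frequencies diverge by a
#' Balding-Nichols model with divergence `fst`, biallelic SNP and INDEL
#' variants with a uniform target MAF spectrum, and block-wise linkage
#' disequilibrium from a latent equicorrelated-Gaussian threshold model.
#'
#' @param n_individuals number of samples.
#' @param n_snp,n_indel number of SNP / INDEL variants. INDELs are ordinary
#'   biallelic dosages labelled `type = "INDEL"` (they enter relationship
#'   matrices exactly like SNPs).
#' @param n_subpop number of subpopulations (default 3, one per sire line).
#' @param fst Balding-Nichols divergence in `[0, 1)`; 0 gives a homogeneous
#'   population.
#' @param block_size variants per LD block.
#' @param within_block_corr latent correlation within a block, in `[0, 1)`;
#'   blocks are mutually independent.
#' @param maf_range target ancestral allele-frequency range `(min, max)`,
#'   min at least 0.01 by default so QC keeps most variants.
#' @param missing_rate fraction of dosages set missing uniformly at random.
#' @param n_chrom number of chromosomes variants are laid out on (pig
#'   autosomes by default); whole LD blocks are kept intra-chromosomal and
#'   variants are spaced 1 kb apart.
#' @param seed integer seed; all generator output is reproducible given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1469, n_snp = 10000, n_indel = 1000,
                       n_subpop = 3, fst = 0.10, block_size = 20,
                       within_block_corr = 0.7, maf_range = c(0.05, 0.5),
                       missing_rate = 0, n_chrom = 18, seed = 1) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snp = as.integer(n_snp), n_indel = as.integer(n_indel),
              n_subpop = as.integer(n_subpop), fst = fst,
              block_size = as.integer(block_size),
              within_block_corr = within_block_corr,
              maf_range = maf_range, missing_rate = missing_rate,
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_individuals > 0, n_snp + n_indel > 0, n_indel >= 0,
              n_subpop > 0, block_size > 0, n_chrom > 0,
              fst >= 0, fst < 1,
              within_block_corr >= 0, within_block_corr < 1,
              missing_rate >= 0, missing_rate < 1,
              length(maf_range) == 2, maf_range[1] > 0,
              maf_range[1] <= maf_range[2], maf_range[2] <= 0.5)
  })
  if (cfg$block_size > cfg$n_snp + cfg$n_indel)
    stop("block_size exceeds the total number of variants")
  structure(cfg, class = "sim_config")
}

#' Simulate genotypes for an admixed population
#'
#' Ancestral allele frequencies are drawn uniformly on `maf_range`;
#' subpopulation frequencies follow Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draws. Each individual receives two
#' latent Gaussian gametes per LD block with equicorrelation
#' `within_block_corr`; alleles arise by thresholding at the subpopulation
#' frequency quantile, so every variant is in Hardy-Weinberg proportion
#' within its subpopulation while dosage correlation persists within blocks.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [geno_matrix()] carrying `subpop` labels) and
#'   `panel` (its [as_variant_panel()] variant table).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$n_snp + cfg$n_indel
  withr::with_seed(cfg$seed, {
    n <- cfg$n_individuals
    S <- cfg$n_subpop
    subpop <- sample(rep(seq_len(S), length.out = n))
    p_anc <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    if (cfg$fst > 0) {
      f <- cfg$fst
      P <- matrix(0, S, m)
      for (s in seq_len(S)) {
        ps <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
        P[s, ] <- pmin(pmax(ps, 0.005), 0.995)
      }
    } else {
      P <- matrix(p_anc, S, m, byrow = TRUE)
    }
    thr <- qnorm(P)                       # S x m threshold matrix
    n_blocks <- ceiling(m / cfg$block_size)
    block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(m)]
    rho <- cfg$within_block_corr
    dos <- matrix(0L, n, m)
    for (h in 1:2) {                      # two gametes
      for (b in seq_len(n_blocks)) {
        j <- which(block_of == b)
        z <- sqrt(rho) * rnorm(n) +
          sqrt(1 - rho) * matrix(rnorm(n * length(j)), n)
        dos[, j] <- dos[, j] + (z < thr[subpop, j, drop = FALSE])
      }
    }
    storage.mode(dos) <- "double"
    if (cfg$missing_rate > 0)
      dos[runif(n * m) < cfg$missing_rate] <- NA
    # layout: contiguous runs of whole blocks per chromosome, 1 kb spacing
    chrom_of_block <- sort(rep(seq_len(cfg$n_chrom), length.out = n_blocks))
    chrom <- chrom_of_block[block_of]
    pos <- unlist(lapply(split(seq_len(m), chrom), function(j)
      1000L * seq_along(j)), use.names = FALSE)
    indel <- rep(FALSE, m)
    if (cfg$n_indel > 0) indel[sample.int(m, cfg$n_indel)] <- TRUE
    variants <- data.frame(
      variant_id = sprintf("%d_%d", chrom, pos),
      chrom = chrom, pos = pos,
      type = ifelse(indel, "INDEL", "SNP"),
      ref = "A", alt = ifelse(indel, "AC", "C"),
      stringsAsFactors = FALSE)
    rownames(dos) <- sprintf("ind%04d", seq_len(n))
    gm <- geno_matrix(dos, variants, subpop = subpop)
    list(gm = gm, panel = gm$variants)
  })
}

#' Configuration for the synthetic trait generator
#'
#' Defines an additive polygenic trait with (optionally) two genomic
#' components - one carried by SNPs, one by INDELs - plus fixed effects of
#' farm, sex and slaughter batch, and a Gaussian residual.
#'
#' @param h2_snp,h2_indel target variance fraction of the SNP / INDEL
#'   component; their sum must be below 1.
#' @param n_causal_snp,n_causal_indel number of causal variants per
#'   component.
#' @param fixed_effects named list of per-level effect vectors, one entry per
#'   factor. Defaults mirror a four-farm, two-sex, thirteen-batch design.
#' @param residual_var residual variance on the trait scale.
#' @param intercept trait grand intercept.
#' @param seed integer seed.
#' @return a `trait_config` list.
#' @export
trait_config <- function(h2_snp = 0.3, h2_indel = 0,
                         n_causal_snp = 100, n_causal_indel = 0,
                         fixed_effects = list(
                           farm = c(0, 2, -1, 3),
                           sex = c(0, 0.5),
                           batch = round(seq(-0.6, 0.6, length.out = 13), 3)),
                         residual_var = 1, intercept = 10, seed = 1) {
  stopifnot(h2_snp >= 0, h2_indel >= 0, residual_var > 0,
            n_causal_snp >= 0, n_causal_indel >= 0)
  if (h2_snp + h2_indel >= 1)
    stop("h2_snp + h2_indel must be < 1")
  if (h2_snp > 0 && n_causal_snp == 0)
    stop("h2_snp > 0 requires causal SNPs")
  if (h2_indel > 0 && n_causal_indel == 0)
    stop("h2_indel > 0 requires causal INDELs")
  structure(list(h2_snp = h2_snp, h2_indel = h2_indel,
                 n_causal_snp = as.integer(n_causal_snp),
                 n_causal_indel = as.integer(n_causal_indel),
                 fixed_effects = fixed_effects,
                 residual_var = residual_var, intercept = intercept,
                 seed = as.integer(seed)),
            class = "trait_config")
}

#' Simulate an additive polygenic phenotype
#'
#' Causal variants are drawn per type; effects are standard-normal draws
#' rescaled so each component's realized breeding-value variance hits its
#' target exactly in-sample (target phenotypic variance is
#' `residual_var / (1 - h2_snp - h2_indel)`). Factor levels are assigned
#' uniformly at random. Phenotype = intercept + fixed effects + BV_snp +
#' BV_indel + residual.
#'
#' @param gm a [geno_matrix()].
#' @param tc a [trait_config()].
#' @param trait_name column name for the simulated trait.
#' @return list with `pheno` (data.frame `id`, trait, `farm`, `sex`,
#'   `batch`) and `truth` (a `sim_truth` list: per-component breeding
#'   values, causal effects, realized per-component variance fractions,
#'   fixed-effect values).
#' @export
simulate_phenotypes <- function(gm, tc, trait_name = "trait") {
  stopifnot(inherits(gm, "geno_matrix"), inherits(tc, "trait_config"))
  n <- nrow(gm$dosage)
  avail <- table(factor(gm$variants$type, levels = c("SNP", "INDEL")))
  if (tc$n_causal_snp > avail[["SNP"]] || tc$n_causal_indel > avail[["INDEL"]])
    stop("causal counts exceed available variants of that type")
  withr::with_seed(tc$seed, {
    # mean-impute missing dosages so BVs are defined for everyone
    X <- gm$dosage
    if (anyNA(X)) {
      p2 <- 2 * alt_freq(X)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- p2[idx[, 2]]
    }
    component_bv <- function(type, n_causal, h2, var_p) {
      out <- list(bv = rep(0, n), effects = numeric(0), causal = character(0))
      if (h2 <= 0 || n_causal == 0) return(out)
      cand <- which(gm$variants$type == type & gm$variants$maf > 0)
      j <- sort(sample(cand, n_causal))
      beta <- rnorm(n_causal)
      bv <- drop(X[, j, drop = FALSE] %*% beta)
      s <- sd(bv)
      if (s < 1e-12) stop("degenerate causal genotypes; cannot scale effects")
      scale <- sqrt(h2 * var_p) / s
      bv <- (bv - mean(bv)) * scale
      list(bv = bv, effects = beta * scale,
           causal = gm$variants$variant_id[j])
    }
    denom <- 1 - tc$h2_snp - tc$h2_indel
    var_p <- tc$residual_var / denom
    comp_s <- component_bv("SNP", tc$n_causal_snp, tc$h2_snp, var_p)
    comp_i <- component_bv("INDEL", tc$n_causal_indel, tc$h2_indel, var_p)
    fx <- lapply(tc$fixed_effects, function(eff)
      sample.int(length(eff), n, replace = TRUE))
    fixed_part <- rep(0, n)
    for (f in names(fx)) fixed_part <- fixed_part + tc$fixed_effects[[f]][fx[[f]]]
    e <- rnorm(n, 0, sqrt(tc$residual_var))
    y <- tc$intercept + fixed_part + comp_s$bv + comp_i$bv + e
    pheno <- data.frame(id = rownames(gm$dosage), y = y,
                        stringsAsFactors = FALSE)
    names(pheno)[2] <- trait_name
    for (f in names(fx))
      pheno[[f]] <- factor(paste0(f, fx[[f]]),
                           levels = paste0(f, seq_along(tc$fixed_effects[[f]])))
    truth <- structure(list(
      true_breeding_values = data.frame(
        id = pheno$id, bv_snp = comp_s$bv, bv_indel = comp_i$bv,
        bv_total = comp_s$bv + comp_i$bv, stringsAsFactors = FALSE),
      causal_effects = list(
        snp = setNames(comp_s$effects, comp_s$causal),
        indel = setNames(comp_i$effects, comp_i$causal)),
      true_h2 = c(snp = tc$h2_snp, indel = tc$h2_indel),
      realized_h2 = c(snp = var(comp_s$bv) / var(y - fixed_part),
                      indel = var(comp_i$bv) / var(y - fixed_part)),
      fixed_effect_values = tc$fixed_effects,
      residual = e), class = "sim_truth")
    list(pheno = pheno, truth = truth)
  })
}

#' Inject genotype errors mimicking imperfect imputation
#'
#' A fraction of the non-missing entries is replaced by a fresh draw from
#' the variant's Hardy-Weinberg genotype distribution (at its alternate
#' allele frequency). `mode = "maf_weighted"` makes the per-variant error
#' rate proportional to MAF (normalised so the average rate equals
#' `error_rate`), concentrating errors on common variants - the regime in
#' which empirical imputation concordance drops.
#'
#' @param gm a [geno_matrix()] (the truth).
#' @param error_rate average fraction of entries corrupted, in `[0, 1]`.
#' @param mode `"uniform"` or `"maf_weighted"`.
#' @param seed integer seed.
#' @return a `geno_matrix` of the same shape, the "imputed" member of a
#'   truth/imputed pair.
#' @export
corrupt_genotypes <- function(gm, error_rate, mode = c("uniform", "maf_weighted"),
                              seed = 1) {
  stopifnot(inherits(gm, "geno_matrix"), error_rate >= 0, error_rate <= 1)
  mode <- match.arg(mode)
  if (error_rate == 0) return(gm)
  withr::with_seed(as.integer(seed), {
    X <- gm$dosage
    n <- nrow(X); m <- ncol(X)
    p <- alt_freq(X)
    rate <- if (mode == "uniform") rep(error_rate, m) else {
      w <- gm$variants$maf / mean(gm$variants$maf)
      pmin(1, error_rate * w)
    }
    hit <- matrix(runif(n * m), n) < rep(rate, each = n)
    hit[is.na(X)] <- FALSE
    idx <- which(hit)
    if (length(idx)) {
      pj <- p[(idx - 1L) %/% n + 1L]
      u <- runif(length(idx))
      # HWE genotype draw: P(0)=(1-p)^2, P(1)=2p(1-p), P(2)=p^2
      g <- ifelse(u < (1 - pj)^2, 0, ifelse(u < (1 - pj)^2 + 2 * pj * (1 - pj), 1, 2))
      X[idx] <- g
    }
    geno_matrix(X, gm$variants[, setdiff(names(gm$variants),
                                         c("maf", "call_rate")), drop = FALSE],
                subpop = gm$subpop)
  })
}

#' Hold out a random sample subset
#'
#' Partitions the samples into a held-out set of `round(fraction * n)`
#' individuals and the remainder, e.g. to form the target population of an
#' imputation-accuracy evaluation (20% of the cohort by default).
#'
#' @param x a [geno_matrix()] or a character vector of sample ids.
#' @param fraction fraction held out, in `(0, 1)`.
#' @param seed integer seed.
#' @return list with `held` and `kept` id vectors (disjoint, exhaustive).
#' @export
hold_out_samples <- function(x, fraction = 0.2, seed = 1) {
  ids <- if (inherits(x, "geno_matrix")) sample_ids(x) else as.character(x)
  stopifnot(fraction > 0, fraction < 1)
  n <- length(ids)
  if (n < 2) stop("need at least 2 samples to hold out a subset")
  k <- round(fraction * n)
  k <- max(1L, min(n - 1L, k))
  withr::with_seed(as.integer(seed), {
    held <- sort(sample(ids, k))
    list(held = held, kept = setdiff(ids, held))
  })
}
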