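test_that("qc_filter applies strict call-rate and MAF rules", {
  X <- cbind(c(rep(1, 6), rep(NA, 4)),   # call rate 0.6 -> removed
             rep(0, 10),                 # monomorphic -> removed
             rep(c(0, 1), 5))            # maf 0.25, full calls -> kept
  gm <- gm_from(X)
  out <- qc_filter(gm)
  expect_equal(out$variants$variant_id, "v003")
  rep_ <- attr(out, "qc_report")
  expect_equal(unname(rep_[c("n_input", "n_kept")]), c(3, 1))
  # identity case: all variants clean
  clean <- gm_from(matrix(rep(c(0, 1), 10), 10, 2))
  expect_equal(qc_filter(clean)$variants$variant_id, clean$variants$variant_id)
  # boundary is strict: call rate exactly at threshold is removed
  Xb <- cbind(c(rep(1, 9), NA), rep(c(0, 1), 5))
  expect_equal(nrow(qc_filter(gm_from(Xb), min_call_rate = 0.9)$variants), 1)
  expect_warning(qc_filter(gm_from(matrix(0, 5, 2))), "every variant")
})

test_that("qc_filter is idempotent", {
  ds <- sim_dataset(n = 120, n_snp = 400, missing = 0.08, seed = 21)
  once <- qc_filter(ds$gm)
  twice <- qc_filter(once)
  expect_identical(twice$variants$variant_id, once$variants$variant_id)
  expect_identical(twice$dosage, once$dosage)
})

test_that("thin_variants: identity, exact cardinality, order, errors", {
  ds <- sim_dataset(n = 50, n_snp = 500, seed = 3)
  all_kept <- thin_variants(ds$gm, "bernoulli", fraction = 1, seed = 1)
  expect_identical(all_kept$variant_id, ds$gm$variants$variant_id)
  p <- thin_variants(ds$gm, "exact", count = 100, seed = 2)
  expect_equal(nrow(p), 100)
  expect_identical(p$variant_id,
                   ds$gm$variants$variant_id[ds$gm$variants$variant_id %in%
                                               p$variant_id])
  expect_error(thin_variants(ds$gm, "exact", count = 10000), "exceeds")
  expect_identical(thin_variants(ds$gm, "exact", count = 100, seed = 2), p)
})

test_that("bernoulli thinning is binomial (3-SD band across 100 seeds)", {
  m <- 10000
  panel <- data.frame(variant_id = sprintf("v%05d", 1:m), chrom = 1L,
                      pos = seq_len(m), type = "SNP", ref = "A", alt = "C")
  sd3 <- 3 * sqrt(m * 0.25)
  inside <- vapply(1:100, function(s)
    abs(nrow(thin_variants(panel, "bernoulli", fraction = 0.5, seed = s)) -
          m / 2) <= sd3, logical(1))
  expect_gte(sum(inside), 99)
})

test_that("exact thinning commutes with QC when thresholds already hold", {
  ds <- sim_dataset(n = 200, n_snp = 300, missing = 0, seed = 31)
  clean <- qc_filter(ds$gm)                 # establish thresholds hold
  a <- thin_variants(qc_filter(clean), "exact", count = 50, seed = 5)
  b <- qc_filter(subset_geno(clean,
         variants = thin_variants(clean, "exact", count = 50, seed = 5)$variant_id))
  expect_identical(a$variant_id, b$variants$variant_id)
})

test_that("ld_prune collapses perfect LD to a single variant", {
  x <- sample(0:2, 100, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  gm <- gm_from(matrix(rep(x, 10), 100, 10))
  kept <- ld_prune(gm, window = 10, step = 5, r2_threshold = 0.6)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$variant_id, "v001")  # equal MAF: later copies removed
})

test_that("ld_prune keeps nearly all independent variants", {
  sim <- simulate_genotypes(sim_config(
    n_individuals = 2000, n_snp = 200, n_indel = 0, fst = 0,
    within_block_corr = 0, seed = 13))
  kept <- ld_prune(sim$gm, window = 50, step = 10, r2_threshold = 0.6)
  expect_gte(nrow(kept), 0.99 * 200)
})

test_that("ld_prune matches a brute-force greedy oracle on one window", {
  set.seed(17)
  n <- 400
  z <- matrix(rnorm(n * 6), n)
  z[, 2] <- z[, 1] + rnorm(n, 0, 0.3)     # strong LD pair
  z[, 5] <- z[, 4] + rnorm(n, 0, 0.4)
  X <- apply(z, 2, function(col) as.numeric(cut(col, c(-Inf,
    quantile(col, c(0.36, 0.84)), Inf))) - 1)
  gm <- gm_from(X)
  got <- ld_prune(gm, window = 6, step = 6, r2_threshold = 0.3)$variant_id
  # independent re-implementation of the documented rule
  keep <- rep(TRUE, 6)
  maf <- gm$variants$maf
  repeat {
    act <- which(keep)
    r2 <- cor(X[, act, drop = FALSE])^2
    viol <- which(upper.tri(r2) & r2 >= 0.3, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    o <- order(viol[, 2], viol[, 1])[1]
    i <- act[viol[o, 1]]; j <- act[viol[o, 2]]
    drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else j
    keep[drop] <- FALSE
  }
  expect_identical(got, gm$variants$variant_id[keep])
})

test_that("ld_prune output is a fixpoint subset and skips monomorphics", {
  ds <- sim_dataset(n = 300, n_snp = 300, rho = 0.85, block = 15, seed = 23)
  X <- ds$gm$dosage
  X[, 7] <- 0                                  # monomorphic column
  gm <- gm_from(X, chrom = ds$gm$variants$chrom, pos = ds$gm$variants$pos)
  kept <- ld_prune(gm, window = 20, step = 5, r2_threshold = 0.5)
  expect_true(all(kept$variant_id %in% gm$variants$variant_id))
  expect_lt(nrow(kept), nrow(gm$variants))
  expect_true("v007" %in% kept$variant_id)     # undefined r2 -> retained
  again <- ld_prune(subset_geno(gm, variants = kept$variant_id),
                    window = 20, step = 5, r2_threshold = 0.5)
  expect_identical(again$variant_id, kept$variant_id)
})

test_that("intersect_panels matches on chrom/pos/ref/alt, keeps a's order", {
  ds <- sim_dataset(n = 20, n_snp = 50, n_indel = 10, seed = 4)
  p <- ds$panel
  expect_identical(intersect_panels(p, p)$variant_id, p$variant_id)
  a <- p[1:5, ]
  b <- p[c(2, 4, 5, 9, 30), ]
  got <- intersect_panels(a, b)
  expect_identical(got$variant_id, p$variant_id[c(2, 4, 5)])
  rep_ <- attr(got, "intersect_report")
  expect_equal(unname(rep_[["n_shared"]]), 3)
  disj <- intersect_panels(p[1:5, ], p[6:10, ])
  expect_equal(nrow(disj), 0)
  # commutative membership, associative membership
  x <- intersect_panels(a, b)$variant_id
  y <- intersect_panels(b, a)$variant_id
  expect_setequal(x, y)
  dup <- rbind(p[1, ], p[1, ])
  dup$variant_id <- c("d1", "d2")
  expect_error(intersect_panels(dup, p), "duplicate")
})
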