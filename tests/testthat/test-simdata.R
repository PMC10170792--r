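test_that("simulate_genotypes honours the shape contract and validates config", {
  sim <- simulate_genotypes(sim_config(n_individuals = 2, n_snp = 1,
                                       n_indel = 0, block_size = 1, seed = 1))
  expect_equal(dim(sim$gm$dosage), c(2L, 1L))
  expect_true(all(sim$gm$dosage %in% c(0, 1, 2)))
  expect_length(sim$gm$subpop, 2)
  expect_error(sim_config(n_individuals = 10, n_snp = 5, n_indel = 0,
                          block_size = 10), "block_size")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("empirical MAF hits a point target (binomial oracle)", {
  sim <- simulate_genotypes(sim_config(
    n_individuals = 2000, n_snp = 300, n_indel = 0, fst = 0,
    maf_range = c(0.3, 0.3), missing_rate = 0, seed = 7))
  expect_lt(abs(mean(sim$gm$variants$maf) - 0.3), 0.02)
})

test_that("MAF spectrum matches the configured uniform distribution (KS)", {
  sim <- simulate_genotypes(sim_config(
    n_individuals = 500, n_snp = 10000, n_indel = 0, fst = 0,
    within_block_corr = 0, maf_range = c(0.1, 0.4), seed = 11))
  ks <- suppressWarnings(
    stats::ks.test(sim$gm$variants$maf, "punif", 0.1, 0.4))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("within-block LD exceeds between-block LD across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_genotypes(sim_config(
      n_individuals = 1000, n_snp = 60, n_indel = 0, fst = 0,
      block_size = 10, within_block_corr = 0.9, n_chrom = 1, seed = s))
    r2 <- suppressWarnings(cor(sim$gm$dosage)^2)
    blk <- rep(1:6, each = 10)
    same <- outer(blk, blk, `==`) & upper.tri(r2)
    diff <- !outer(blk, blk, `==`) & upper.tri(r2)
    mean(r2[same], na.rm = TRUE) > mean(r2[diff], na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("generator output is bit-identical given the seed", {
  cfg <- sim_config(n_individuals = 50, n_snp = 200, n_indel = 20,
                    missing_rate = 0.05, seed = 42)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  gm <- simulate_genotypes(cfg)$gm
  tc <- trait_config(h2_snp = 0.3, n_causal_snp = 30, seed = 9)
  expect_identical(simulate_phenotypes(gm, tc), simulate_phenotypes(gm, tc))
  expect_identical(corrupt_genotypes(gm, 0.2, seed = 5),
                   corrupt_genotypes(gm, 0.2, seed = 5))
})

test_that("null heritability gives exactly zero breeding values", {
  ds <- sim_dataset(n = 80, n_snp = 200, h2_snp = 0, n_causal_snp = 0)
  expect_identical(var(ds$truth$true_breeding_values$bv_total), 0)
  expect_identical(ds$truth$realized_h2[["snp"]], 0)
})

test_that("realized heritability tracks the target as n grows", {
  for (n in c(200, 2000)) {
    ds <- sim_dataset(n = n, n_snp = 1000, h2_snp = 0.3, n_causal_snp = 100,
                      seed = 3)
    ratio <- var(ds$truth$true_breeding_values$bv_snp) /
      var(ds$truth$true_breeding_values$bv_snp + ds$truth$residual)
    if (n >= 1000) expect_lt(abs(ratio - 0.3), 0.05)
    expect_gt(ratio, 0.15)  # loose sanity at small n
  }
})

test_that("identical genotypes imply identical breeding values", {
  sim <- simulate_genotypes(sim_config(n_individuals = 40, n_snp = 200,
                                       n_indel = 0, seed = 2))
  X <- sim$gm$dosage
  X[2, ] <- X[1, ]
  gm <- geno_matrix(X, sim$gm$variants[, 1:6])
  ph <- simulate_phenotypes(gm, trait_config(h2_snp = 0.4, n_causal_snp = 50,
                                             seed = 3))
  bv <- ph$truth$true_breeding_values
  expect_equal(bv$bv_total[1], bv$bv_total[2])
})

test_that("corrupt_genotypes: identity at rate 0, HWE draws at rate 1", {
  ds <- sim_dataset(n = 2000, n_snp = 30, missing = 0, seed = 5)
  expect_identical(corrupt_genotypes(ds$gm, 0, seed = 1), ds$gm)
  # rate 1 at p = 0.5: expected concordance 0.25^2 + 0.5^2 + 0.25^2 = 0.375
  sim <- simulate_genotypes(sim_config(
    n_individuals = 2000, n_snp = 30, n_indel = 0, fst = 0,
    maf_range = c(0.5, 0.5), within_block_corr = 0, seed = 6))
  bad <- corrupt_genotypes(sim$gm, 1, seed = 7)
  cr <- mean(bad$dosage == sim$gm$dosage)
  expect_lt(abs(cr - 0.375), 0.015)
})

test_that("maf_weighted corruption concentrates errors on common variants", {
  sim <- simulate_genotypes(sim_config(
    n_individuals = 800, n_snp = 400, n_indel = 0, fst = 0,
    within_block_corr = 0, maf_range = c(0.01, 0.5), seed = 8))
  bad <- corrupt_genotypes(sim$gm, 0.1, mode = "maf_weighted", seed = 9)
  err <- colMeans(bad$dosage != sim$gm$dosage)
  expect_gt(cor(err, sim$gm$variants$maf), 0.5)
})

test_that("hold_out_samples partitions deterministically", {
  ids <- sprintf("s%04d", 1:1469)
  h <- hold_out_samples(ids, 0.2, seed = 1)
  expect_length(h$held, 294)           # round(0.2 * 1469)
  expect_length(hold_out_samples(sprintf("s%d", 1:10), 0.2, seed = 1)$held, 2)
  expect_setequal(c(h$held, h$kept), ids)
  expect_length(intersect(h$held, h$kept), 0)
  expect_identical(h, hold_out_samples(ids, 0.2, seed = 1))
  expect_error(hold_out_samples("one", 0.2), "at least 2")
})
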