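test_that("gblup degenerates gracefully when genetic variance is floored", {
  ds <- sim_dataset(n = 50, n_snp = 200, seed = 24)
  g <- compute_grm(ds$gm)
  y <- yc_of(ds)
  p <- gblup_predict(y, g, names(y)[1:40], variances = c(1e-12, 1))
  expect_true(all(p$gebv == 0))
  expect_equal(p$mu_hat, mean(y[1:40]))
})

test_that("a predict individual with zero genomic covariance gets GEBV 0", {
  n <- 20
  set.seed(25)
  V <- crossprod(matrix(rnorm(n * n), n)) / n
  V[n, ] <- 0; V[, n] <- 0; V[n, n] <- 1
  ids <- sprintf("s%02d", 1:n)
  g <- structure(list(values = `dimnames<-`(V, list(ids, ids)),
                      sample_ids = ids, n_markers = 100L,
                      algorithm = "vanraden1"), class = "grm")
  y <- setNames(rnorm(n - 1), ids[-n])
  p <- gblup_predict(y, g, train_ids = ids[-n], variances = c(0.5, 1))
  expect_lt(abs(p$gebv[[ids[n]]]), 1e-10)
})

test_that("MME and closed-form V-inverse solutions agree (30 samples)", {
  ds <- sim_dataset(n = 30, n_snp = 150, h2_snp = 0.4, seed = 26)
  g <- compute_grm(ds$gm)
  y <- yc_of(ds)
  tr <- names(y)[1:22]
  a <- gblup_predict(y, g, tr, variances = c(0.6, 0.9), method = "mme")
  b <- gblup_predict(y, g, tr, variances = c(0.6, 0.9), method = "vinv")
  expect_lt(max(abs(a$gebv - b$gebv)), 1e-8)
  expect_lt(abs(a$mu_hat - b$mu_hat), 1e-8)
})

test_that("gblup is equivariant under phenotype shifts", {
  ds <- sim_dataset(n = 60, n_snp = 200, h2_snp = 0.4, seed = 27)
  g <- compute_grm(ds$gm)
  y <- yc_of(ds)
  tr <- names(y)[1:45]
  p1 <- gblup_predict(y, g, tr, variances = c(0.5, 1))
  p2 <- gblup_predict(y + 7, g, tr, variances = c(0.5, 1))
  expect_equal(p2$mu_hat, p1$mu_hat + 7, tolerance = 1e-8)
  expect_lt(max(abs(p2$gebv - p1$gebv)), 1e-8)
})

test_that("multiblup reductions and symmetry hold", {
  ds <- sim_dataset(n = 60, n_snp = 250, n_indel = 60, h2_snp = 0.3,
                    h2_indel = 0.1, n_causal_snp = 60, n_causal_indel = 15,
                    seed = 28)
  g_snp <- compute_grm(subset_geno(ds$gm,
             variants = which(ds$gm$variants$type == "SNP")))
  g_ind <- compute_grm(subset_geno(ds$gm,
             variants = which(ds$gm$variants$type == "INDEL")))
  y <- yc_of(ds)
  tr <- names(y)[1:45]
  base <- gblup_predict(y, g_snp, tr, variances = c(0.7, 1), method = "vinv")
  m1 <- multiblup_predict(y, g_ind, g_snp, tr, variances = c(1e-12, 0.7, 1))
  expect_lt(max(abs(m1$gebv - base$gebv)), 1e-6)
  m2 <- multiblup_predict(y, g_snp, g_snp, tr, variances = c(0.3, 0.4, 1))
  expect_lt(max(abs(m2$gebv - base$gebv)), 1e-6)
  s1 <- multiblup_predict(y, g_ind, g_snp, tr, variances = c(0.2, 0.5, 1))
  s2 <- multiblup_predict(y, g_snp, g_ind, tr, variances = c(0.5, 0.2, 1))
  expect_equal(s1$components$g_f, s2$components$g_r)
  expect_equal(s1$components$g_r, s2$components$g_f)
  expect_lt(max(abs(s1$components$g_f + s1$components$g_r - s1$gebv)), 1e-12)
})

test_that("accuracy and bias_slope follow their definitions", {
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(accuracy(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1)
  x <- c(1, 2, 3, 4); gv <- c(2, 1, 3, 4)
  manual <- sum((x - mean(x)) * (gv - mean(gv))) /
    sqrt(sum((x - mean(x))^2) * sum((gv - mean(gv))^2))
  expect_equal(accuracy(x, gv), manual)
  expect_warning(accuracy(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_equal(bias_slope(x, x), 1)
  expect_equal(bias_slope(x, 0.5 * x), 2)
  expect_equal(bias_slope(x, 0.5 * x + 10), 2)   # location invariance
  expect_warning(bias_slope(x, rep(2, 4)), "zero GEBV variance")
})

test_that("cross_validate yields reps*k rounds, balanced folds, determinism", {
  ds <- sim_dataset(n = 60, n_snp = 200, h2_snp = 0.4, seed = 29)
  g <- compute_grm(ds$gm)
  y <- yc_of(ds)
  cv <- cross_validate(y, subset_grm(g, names(y)), k = 5, reps = 5, seed = 3,
                       refit_variances = FALSE, variances = c(0.5, 1))
  expect_equal(nrow(cv$rounds), 25)
  per_rep <- tapply(cv$rounds$n_validation, cv$rounds$repetition, sum)
  expect_true(all(per_rep == 60))
  expect_lte(max(cv$rounds$n_validation) - min(cv$rounds$n_validation), 1)
  cv2 <- cross_validate(y, subset_grm(g, names(y)), k = 5, reps = 5, seed = 3,
                        refit_variances = FALSE, variances = c(0.5, 1))
  expect_identical(cv$rounds, cv2$rounds)
  expect_error(cross_validate(y, subset_grm(g, names(y)), k = 1), "k")
})

test_that("null-heritability CV accuracy is indistinguishable from zero", {
  sim <- simulate_genotypes(sim_config(n_individuals = 150, n_snp = 300,
                                       n_indel = 0, seed = 31))
  g <- compute_grm(sim$gm)
  y <- setNames(rnorm(150), rownames(sim$gm$dosage))
  cv <- cross_validate(y, g, k = 5, reps = 2, seed = 5,
                       refit_variances = FALSE, variances = c(0.02, 1))
  se <- cv$summary$sd_accuracy / sqrt(nrow(cv$rounds))
  expect_lt(abs(cv$summary$mean_accuracy), 2 * se + 0.1)
})

test_that("percent_increase reporting convention", {
  expect_equal(percent_increase(0.2, 0.2), 0)
  expect_equal(percent_increase(0.3, 0.4), 33.33)
  expect_error(percent_increase(0, 0.1), "baseline")
})
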