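#' GBLUP breeding-value prediction
#'
#' Solves the single-component mixed model `y = 1 mu + Z g + e`,
#' `g ~ N(0, G s_g)`, `e ~ N(0, I s_e)` for the training individuals and
#' returns genomic values for every individual in the GRM (including
#' unphenotyped ones). The default `"mme"` method solves Henderson's
#' equations premultiplied by `G` (no explicit `G` inverse, so singular
#' relationship matrices are fine); `"vinv"` is the closed form
#' `g_hat = s_g G Z' V^{-1} (y - 1 mu_hat)` with
#' `V = s_g Z G Z' + s_e I`, retained as an independent cross-check. The
#' two agree to numerical precision.
#'
#' @param yc named numeric vector of corrected phenotypes for (at least)
#'   the training individuals.
#' @param grm a `grm` covering training and prediction individuals.
#' @param train_ids ids used to fit the model.
#' @param predict_ids ids to report (default: every id in the GRM).
#' @param variances a [reml_fit()] result, or a numeric vector
#'   `c(sigma_g, sigma_e)`.
#' @param method `"mme"` or `"vinv"`.
#' @return object of class `gp_prediction`: `gebv` (named, over all GRM
#'   ids), `predicted` (subset for `predict_ids`), `mu_hat`,
#'   `variances_used`, `model`.
#' @export
gblup_predict <- function(yc, grm, train_ids, predict_ids = NULL,
                          variances, method = c("mme", "vinv")) {
  method <- match.arg(method)
  v <- extract_variances(variances, n_genomic = 1)
  ids <- grm$sample_ids
  stopifnot(all(train_ids %in% ids))
  if (is.null(predict_ids)) predict_ids <- ids
  stopifnot(all(predict_ids %in% ids))
  y <- yc[train_ids]
  if (anyNA(y)) stop("missing phenotypes among training ids")
  G <- grm$values
  tr <- match(train_ids, ids)
  N <- length(ids)
  s_g <- v[1]; s_e <- v[2]
  if (s_g <= 1e-12 * (s_g + s_e)) {
    gebv <- setNames(rep(0, N), ids)
    mu <- mean(y)
  } else if (method == "vinv") {
    Vtt <- s_g * G[tr, tr] + diag(s_e, length(tr))
    Vi <- solve_spd(Vtt)
    one <- rep(1, length(tr))
    mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
    gebv <- setNames(drop(s_g * G[, tr] %*% (Vi %*% (y - mu))), ids)
  } else {
    # Henderson's equations premultiplied by G: G-inverse-free, exact for
    # singular G.  Unknowns (mu, g_1..g_N); row 1 is the fixed-effect
    # equation, rows 2..N+1 are  G Z'1 mu + (G Z'Z + lambda I) g = G Z'y.
    lambda <- s_e / s_g
    t_n <- length(tr)
    ind <- numeric(N); ind[tr] <- 1
    Gt <- G[, tr, drop = FALSE]
    C <- matrix(0, N, N)
    C[, tr] <- Gt
    diag(C) <- diag(C) + lambda
    A <- rbind(c(t_n, ind), cbind(rowSums(Gt), C))
    b <- c(sum(y), drop(Gt %*% y))
    sol <- solve_with_jitter(A, b)
    mu <- sol[1]
    gebv <- setNames(sol[-1], ids)
  }
  structure(list(gebv = gebv, predicted = gebv[predict_ids],
                 components = NULL, mu_hat = mu,
                 variances_used = c(sigma_g = s_g, sigma_e = s_e),
                 model = "gblup"),
            class = "gp_prediction")
}

solve_spd <- function(M) chol2inv(chol((M + t(M)) / 2))

solve_with_jitter <- function(A, b) {
  tryCatch(solve(A, b), error = function(e) {
    diag(A) <- diag(A) + 1e-8 * mean(abs(diag(A)))
    solve(A, b)   # one jitter; errors propagate if still singular
  })
}

extract_variances <- function(variances, n_genomic) {
  if (inherits(variances, "variance_estimate")) {
    comp <- variances$components
    if (length(comp) != n_genomic + 1)
      stop("variance estimate has ", length(comp) - 1,
           " genomic components; model needs ", n_genomic)
    return(as.numeric(comp))
  }
  v <- as.numeric(variances)
  if (length(v) != n_genomic + 1)
    stop("expected ", n_genomic + 1, " variances (genomic then residual)")
  if (any(v < 0)) stop("variances must be >= 0")
  v
}

#' MultiBLUP prediction with two genomic components
#'
#' Joint BLUP of two random genomic effects (e.g. one captured by INDELs,
#' one by SNPs) under
#' `V = s_gf G_f + s_gr G_r + s_e I`; each component is projected as
#' `g_hat = s G[, train] V^{-1} (y - 1 mu_hat)` and the total genomic value
#' is their sum.
#'
#' @param yc named numeric vector of corrected phenotypes.
#' @param grm_f,grm_r `grm` objects for the two components on a common id
#'   set (conventionally `f` = INDEL, `r` = SNP).
#' @param train_ids,predict_ids as in [gblup_predict()].
#' @param variances a two-component [reml_fit()] result or numeric
#'   `c(sigma_gf, sigma_gr, sigma_e)`.
#' @return `gp_prediction` with `components` (`g_f`, `g_r`) summing to
#'   `gebv`.
#' @export
multiblup_predict <- function(yc, grm_f, grm_r, train_ids,
                              predict_ids = NULL, variances) {
  v <- extract_variances(variances, n_genomic = 2)
  ids <- grm_f$sample_ids
  if (!identical(ids, grm_r$sample_ids))
    stop("the two GRMs must share one sample id set")
  stopifnot(all(train_ids %in% ids))
  if (is.null(predict_ids)) predict_ids <- ids
  y <- yc[train_ids]
  if (anyNA(y)) stop("missing phenotypes among training ids")
  tr <- match(train_ids, ids)
  s_gf <- v[1]; s_gr <- v[2]; s_e <- v[3]
  Vtt <- s_gf * grm_f$values[tr, tr] + s_gr * grm_r$values[tr, tr] +
    diag(s_e, length(tr))
  Vi <- tryCatch(solve_spd(Vtt), error = function(e) {
    solve_spd(Vtt + diag(1e-8 * mean(diag(Vtt)), nrow(Vtt)))
  })
  one <- rep(1, length(tr))
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  r <- drop(Vi %*% (y - mu))
  g_f <- setNames(drop(s_gf * grm_f$values[, tr] %*% r), ids)
  g_r <- setNames(drop(s_gr * grm_r$values[, tr] %*% r), ids)
  gebv <- g_f + g_r
  structure(list(gebv = gebv, predicted = gebv[predict_ids],
                 components = list(g_f = g_f, g_r = g_r), mu_hat = mu,
                 variances_used = c(sigma_gf = s_gf, sigma_gr = s_gr,
                                    sigma_e = s_e),
                 model = "multiblup"),
            class = "gp_prediction")
}

#' Prediction accuracy
#'
#' Pearson correlation between corrected phenotypes and genomic values in a
#' validation set.
#'
#' @param yc_validation,gebv_validation numeric vectors (>= 3 pairs, both
#'   with positive variance).
#' @return correlation, or `NA` with a warning when undefined.
#' @export
accuracy <- function(yc_validation, gebv_validation) {
  ok <- complete.cases(yc_validation, gebv_validation)
  x <- yc_validation[ok]; g <- gebv_validation[ok]
  if (length(x) < 3) { warning("fewer than 3 pairs; accuracy undefined"); return(NA_real_) }
  if (sd(x) == 0 || sd(g) == 0) {
    warning("zero variance; accuracy undefined"); return(NA_real_)
  }
  cor(x, g)
}

#' Prediction bias (dispersion) slope
#'
#' Least-squares slope of the regression of corrected phenotype on genomic
#' value in the validation set: 1 indicates unbiased dispersion, above 1
#' deflated, below 1 inflated predictions.
#'
#' @inheritParams accuracy
#' @return slope `cov(yc, gebv) / var(gebv)`, or `NA` with a warning.
#' @export
bias_slope <- function(yc_validation, gebv_validation) {
  ok <- complete.cases(yc_validation, gebv_validation)
  x <- yc_validation[ok]; g <- gebv_validation[ok]
  if (length(x) < 3) { warning("fewer than 3 pairs; bias undefined"); return(NA_real_) }
  if (var(g) == 0) { warning("zero GEBV variance; bias undefined"); return(NA_real_) }
  cov(x, g) / var(g)
}

#' Repeated k-fold cross-validated genomic prediction
#'
#' For each repetition the ids are freshly shuffled (seed = `seed` +
#' repetition index) and split into `k` folds of sizes differing by at most
#' one. Each fold in turn is the validation set; variances are re-estimated
#' on the training folds by default (no leakage), or fixed via `variances`
#' when `refit_variances = FALSE` (estimated once on the full data if not
#' supplied). Accuracy and bias are recorded per round and averaged over
#' all `reps * k` rounds.
#'
#' @param yc named numeric vector of corrected phenotypes.
#' @param grms a single `grm` (gblup) or list of two (multiblup: `f` then
#'   `r`).
#' @param model `"gblup"` or `"multiblup"`.
#' @param k folds (>= 2); `reps` repetitions.
#' @param seed integer root seed.
#' @param refit_variances re-estimate variance components per training set.
#' @param variances fixed variances used when `refit_variances = FALSE`.
#' @return object of class `cv_result`: `rounds` data.frame (repetition,
#'   fold, n_validation, accuracy, bias_slope, flagged) and `summary`
#'   (mean/sd of accuracy and bias over rounds).
#' @export
cross_validate <- function(yc, grms, model = c("gblup", "multiblup"),
                           k = 5, reps = 5, seed = 1,
                           refit_variances = TRUE, variances = NULL) {
  model <- match.arg(model)
  if (inherits(grms, "grm")) grms <- list(grms)
  n_comp <- if (model == "gblup") 1 else 2
  if (length(grms) != n_comp)
    stop(model, " needs ", n_comp, " GRM(s), got ", length(grms))
  ids <- names(yc)
  if (is.null(ids)) stop("yc must be named by sample id")
  stopifnot(all(ids %in% grms[[1]]$sample_ids), k >= 2, reps >= 1)
  n <- length(ids)
  if (n < k) stop("need at least k samples")
  if (!refit_variances && is.null(variances))
    variances <- reml_fit(yc, if (n_comp == 1) grms[[1]] else grms)
  rounds <- vector("list", reps * k)
  ri <- 0
  for (rep_i in seq_len(reps)) {
    perm <- withr::with_seed(as.integer(seed) + rep_i, sample(ids))
    fold_id <- rep(seq_len(k), length.out = n)
    for (f in seq_len(k)) {
      ri <- ri + 1
      val <- perm[fold_id == f]
      train <- setdiff(ids, val)
      v_f <- if (refit_variances) {
        tg <- lapply(grms, subset_grm, ids = train)
        reml_fit(yc[train], if (n_comp == 1) tg[[1]] else tg)
      } else variances
      pred <- if (model == "gblup")
        gblup_predict(yc, grms[[1]], train_ids = train, predict_ids = val,
                      variances = v_f)
      else
        multiblup_predict(yc, grms[[1]], grms[[2]], train_ids = train,
                          predict_ids = val, variances = v_f)
      flagged <- length(val) < 3
      acc <- if (flagged) NA_real_ else
        suppressWarnings(accuracy(yc[val], pred$predicted))
      b <- if (flagged) NA_real_ else
        suppressWarnings(bias_slope(yc[val], pred$predicted))
      rounds[[ri]] <- data.frame(repetition = rep_i, fold = f,
                                 n_validation = length(val),
                                 accuracy = acc, bias_slope = b,
                                 flagged = flagged)
    }
  }
  rounds <- do.call(rbind, rounds)
  summ <- data.frame(
    n_rounds = nrow(rounds),
    mean_accuracy = mean(rounds$accuracy, na.rm = TRUE),
    sd_accuracy = sd(rounds$accuracy, na.rm = TRUE),
    mean_bias = mean(rounds$bias_slope, na.rm = TRUE),
    sd_bias = sd(rounds$bias_slope, na.rm = TRUE))
  structure(list(rounds = rounds, summary = summ, model = model,
                 k = k, reps = reps, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d folds x %d repetitions (%d rounds)\n",
              x$model, x$k, x$reps, nrow(x$rounds)))
  cat(sprintf("  mean accuracy %.4f (SD %.4f); mean bias %.4f (SD %.4f)\n",
              x$summary$mean_accuracy, x$summary$sd_accuracy,
              x$summary$mean_bias, x$summary$sd_bias))
  invisible(x)
}

#' Percent increase relative to a baseline
#'
#' The reporting convention for accuracy or heritability gains:
#' `100 * (new - baseline) / baseline`, rounded to two decimals.
#'
#' @param baseline positive baseline value.
#' @param new new value.
#' @return percent change (2 decimals).
#' @export
percent_increase <- function(baseline, new) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  round(100 * (new - baseline) / baseline, 2)
}
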