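#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the REML log-likelihood of `y ~ N(X b, sum_k s_k G_k + s_e I)`
#' up to an additive constant:
#' \deqn{\ell_R = -\tfrac12\left(\log|V| + \log|X^\top V^{-1}X|
#'   + y^\top P y\right).}
#' This single definition is shared by the AI-REML optimizer and by
#' brute-force grid-search oracles, so the two can be compared directly.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default intercept only).
#' @param grms a `grm`, a plain symmetric matrix, or a list of them.
#' @param variances numeric vector of variances: one per genomic component,
#'   then the residual last. All must be >= 0, at least one > 0.
#' @return scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(y, X = NULL, grms, variances) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  Ks <- grm_list_values(grms, n)
  k <- length(Ks)
  stopifnot(length(variances) == k + 1, all(variances >= 0),
            any(variances > 0))
  V <- diag(variances[k + 1], n)
  for (j in seq_len(k)) V <- V + variances[j] * Ks[[j]]
  cV <- tryCatch(chol(V), error = function(e) stop("singular V"))
  Vi <- chol2inv(cV)
  XtVi <- crossprod(X, Vi)
  B <- XtVi %*% X
  cB <- chol(B)
  Py <- Vi %*% y - t(XtVi) %*% solve(B, XtVi %*% y)
  as.numeric(-0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cB))) +
                       crossprod(y, Py)))
}

grm_list_values <- function(grms, n) {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (is.matrix(grms)) grms <- list(grms)
  lapply(grms, function(g) {
    M <- if (inherits(g, "grm")) g$values else as.matrix(g)
    if (!all(dim(M) == n)) stop("GRM dimension does not match y")
    M
  })
}

#' REML estimation of variance components and heritability
#'
#' Fits `y ~ N(X b, sum_k s_k G_k + s_e I)` by average-information REML
#' with expectation-maximization fallback steps (the first `em_iters`
#' iterations, and whenever an AI step is unusable). Negative proposals are
#' truncated to a small positive floor (`1e-8 * var(y)`) and tested for
#' boundary convergence. Convergence requires the maximum relative parameter
#' change below `tol_param` and the log-likelihood change below
#' `tol_loglik`. Standard errors come from the inverse average-information
#' matrix; per-component heritability SEs by the delta method.
#'
#' Single-component fits are computed in the eigenbasis of the GRM, which
#' makes every iteration O(n) after one eigendecomposition; results are
#' identical to the dense path used for multi-component models.
#'
#' @param y named numeric vector of (pre-corrected) phenotypes; names are
#'   matched against GRM sample ids when present.
#' @param grms one `grm` (or matrix) or a list of them (named components).
#' @param X optional fixed-effect design; default intercept only (the
#'   two-stage convention: phenotypes are adjusted upstream).
#' @param max_iter,em_iters iteration controls.
#' @param tol_param,tol_loglik convergence tolerances.
#' @return object of class `variance_estimate`: named `components` (genomic
#'   variances and `residual`), `se`, `h2` (per component and `total`),
#'   `h2_se`, `loglik`, `n_iterations`, `converged`, `n`, `boundary`.
#' @export
reml_fit <- function(y, grms, X = NULL, max_iter = 100, em_iters = 3,
                     tol_param = 1e-6, tol_loglik = 1e-8) {
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  comp_names <- names(grms) %||% if (length(grms) == 1) "g" else
    paste0("g", seq_along(grms))
  # align on ids when both sides carry them
  ids <- names(y)
  if (!is.null(ids) && inherits(grms[[1]], "grm")) {
    grms <- lapply(grms, subset_grm, ids = ids)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  k <- length(grms)
  if (n < k + p + 1) stop("too few observations for the model")
  Ks <- grm_list_values(grms, n)
  vy <- var(y)
  floor_v <- 1e-8 * vy
  theta <- rep(vy / (k + 1), k + 1)

  core <- if (k == 1) reml_core_spectral(y, X, Ks[[1]]) else
    reml_core_dense(y, X, Ks)

  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  AI <- NULL
  for (it in seq_len(max_iter)) {
    q <- core(theta)            # list(loglik, dl, AI, yPGPy, trPG)
    use_em <- it <= em_iters
    theta_new <- NULL
    if (!use_em) {
      # pseudo-inverse handles singular AI (unidentifiable ridges, e.g.
      # duplicated components): steps are taken in identifiable directions
      delta <- tryCatch({
        if (rcond(q$AI) > 1e-10) solve(q$AI, q$dl) else pinv(q$AI) %*% q$dl
      }, error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) use_em <- TRUE
      else theta_new <- theta + as.numeric(delta)
    }
    if (use_em)
      theta_new <- theta + theta^2 * (q$yPGPy - q$trPG) / n
    theta_new <- pmax(theta_new, floor_v)
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    dll <- q$loglik - ll_old
    theta <- theta_new
    AI <- q$AI
    if (it > 1 && rel < tol_param && abs(dll) < tol_loglik) {
      converged <- TRUE
      break
    }
    ll_old <- q$loglik
  }
  q <- core(theta)
  if (!is.finite(q$loglik))
    stop("non-finite restricted likelihood at iteration ", it)
  Cth <- tryCatch(solve(q$AI), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  se <- sqrt(pmax(diag(Cth), 0))
  S <- sum(theta)
  h2 <- theta[seq_len(k)] / S
  h2_total <- sum(theta[seq_len(k)]) / S
  # delta method for h2_j = theta_j / S
  h2_se <- vapply(seq_len(k), function(j) {
    g <- rep(-theta[j] / S^2, k + 1)
    g[j] <- g[j] + 1 / S
    sqrt(max(0, drop(t(g) %*% Cth %*% g)))
  }, numeric(1))
  g_tot <- c(rep(theta[k + 1] / S^2, k), -(S - theta[k + 1]) / S^2)
  h2_total_se <- sqrt(max(0, drop(t(g_tot) %*% Cth %*% g_tot)))
  structure(list(
    components = setNames(theta, c(comp_names, "residual")),
    se = setNames(se, c(comp_names, "residual")),
    h2 = setNames(c(h2, h2_total), c(comp_names, "total")),
    h2_se = setNames(c(h2_se, h2_total_se), c(comp_names, "total")),
    loglik = q$loglik, n_iterations = it, converged = converged,
    n = n, boundary = setNames(theta <= floor_v * (1 + 1e-6),
                               c(comp_names, "residual"))),
    class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat("REML variance components (n =", x$n, ")\n")
  tab <- data.frame(variance = x$components, se = x$se)
  print(round(tab, 5))
  cat(sprintf("h2 total: %.4f (SE %.4f); loglik %.4f; %s in %d iterations\n",
              x$h2[["total"]], x$h2_se[["total"]], x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# --- iteration cores -------------------------------------------------------
# Each core returns, for a variance vector theta (genomic components then
# residual): the restricted log-likelihood, score vector dl, AI matrix, and
# the EM ingredients y'P G_j P y and tr(P G_j) per component (residual G = I).

reml_core_spectral <- function(y, X, K) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  function(theta) {
    w <- theta[1] * d + theta[2]
    wi <- 1 / w
    B <- crossprod(Xt, Xt * wi)
    cB <- chol(B)
    Bi <- chol2inv(cB)
    Pv <- function(v) {
      wv <- wi * v
      wv - wi * drop(Xt %*% (Bi %*% crossprod(Xt, wv)))
    }
    Py <- Pv(yt)
    trP_mat <- function(dd) {   # tr(P diag(dd))
      Tm <- crossprod(Xt, Xt * (dd * wi * wi))
      sum(dd * wi) - sum(Bi * Tm)
    }
    trPG <- c(trP_mat(d), trP_mat(rep(1, length(d))))
    yPGPy <- c(sum(d * Py^2), sum(Py^2))
    u_g <- d * Py
    Pu_g <- Pv(u_g)
    AI <- 0.5 * matrix(c(sum(u_g * Pu_g), sum(Py * Pu_g),
                         sum(Py * Pu_g), sum(Py * Pv(Py))), 2, 2)
    ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(cB))) + sum(yt * Py))
    list(loglik = as.numeric(ll), dl = -0.5 * (trPG - yPGPy),
         AI = AI, yPGPy = yPGPy, trPG = trPG)
  }
}

reml_core_dense <- function(y, X, Ks) {
  n <- length(y)
  k <- length(Ks)
  Ks_all <- c(Ks, list(diag(n)))
  function(theta) {
    V <- diag(theta[k + 1], n)
    for (j in seq_len(k)) V <- V + theta[j] * Ks[[j]]
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtVi <- crossprod(X, Vi)
    B <- XtVi %*% X
    cB <- chol(B)
    P <- Vi - t(XtVi) %*% chol2inv(cB) %*% XtVi
    Py <- drop(P %*% y)
    trPG <- numeric(k + 1)
    yPGPy <- numeric(k + 1)
    u <- vector("list", k + 1)
    for (j in seq_len(k + 1)) {
      G <- Ks_all[[j]]
      trPG[j] <- if (j == k + 1) sum(diag(P)) else sum(P * G)
      u[[j]] <- if (j == k + 1) Py else drop(G %*% Py)
      yPGPy[j] <- sum(Py * u[[j]])
    }
    AI <- matrix(0, k + 1, k + 1)
    Pu <- lapply(u, function(v) drop(P %*% v))
    for (a in seq_len(k + 1))
      for (b in a:(k + 1))
        AI[a, b] <- AI[b, a] <- 0.5 * sum(u[[a]] * Pu[[b]])
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cB))) +
                    sum(y * Py))
    list(loglik = as.numeric(ll), dl = -0.5 * (trPG - yPGPy),
         AI = AI, yPGPy = yPGPy, trPG = trPG)
  }
}

#' Heritability across a panel-density sweep
#'
#' Runs [reml_fit()] once per panel GRM and tabulates heritability against
#' marker density, with the percent change relative to the lowest-density
#' panel appended (the classic density-sweep diagnostic: sparse panels tag
#' causal variation poorly and capture less heritability).
#'
#' @param y named numeric phenotype vector.
#' @param grms_by_panel named list of `grm` objects, one per panel.
#' @param X optional fixed-effect design passed to [reml_fit()].
#' @return data.frame (panel, n_markers, h2, se, converged, pct_change,
#'   note), ordered by increasing marker count. Failed fits are flagged in
#'   `note`, not dropped.
#' @export
h2_profile <- function(y, grms_by_panel, X = NULL) {
  stopifnot(is.list(grms_by_panel), length(grms_by_panel) >= 1,
            !is.null(names(grms_by_panel)))
  ord <- order(vapply(grms_by_panel, `[[`, integer(1), "n_markers"))
  grms_by_panel <- grms_by_panel[ord]
  rows <- lapply(names(grms_by_panel), function(nm) {
    fit <- tryCatch(reml_fit(y, grms_by_panel[[nm]], X = X),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(panel = nm, n_markers = grms_by_panel[[nm]]$n_markers,
                 h2 = NA_real_, se = NA_real_, converged = FALSE,
                 note = conditionMessage(fit), stringsAsFactors = FALSE)
    else
      data.frame(panel = nm, n_markers = grms_by_panel[[nm]]$n_markers,
                 h2 = fit$h2[["total"]], se = fit$h2_se[["total"]],
                 converged = fit$converged, note = "",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- out$h2[1]
  out$pct_change <- if (is.na(base) || base <= 0) NA_real_ else
    round(100 * (out$h2 - base) / base, 2)
  out
}
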