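#' Corrected phenotypes (fixed effects removed)
#'
#' Computes corrected phenotypic values `Yc` for one trait by removing the
#' estimated fixed effects (farm, sex, slaughter batch by default) from the
#' raw values, then restoring the grand mean so `Yc` stays on the trait
#' scale. Two estimators of the fixed effects are offered:
#'
#' * `fixed_only` - ordinary least squares of the trait on the factor
#'   indicators;
#' * `animal_model` - a single-trait animal model: variance components are
#'   estimated by [reml_fit()] with the supplied GRM and the fixed effects
#'   by generalized least squares under the fitted covariance. Only the
#'   fixed part is subtracted in both cases.
#'
#' @param pt phenotype data.frame with columns `id`, the trait, and the
#'   factor columns.
#' @param trait trait column name.
#' @param method `"animal_model"` (default) or `"fixed_only"`.
#' @param grm a `grm` covering all phenotyped samples (required for
#'   `animal_model`).
#' @param factors factor column names used as fixed effects.
#' @return named numeric vector `Yc` (names = sample ids); mean equal to
#'   the trait mean. The fitted fixed-effect coefficients are attached as
#'   attribute `"beta"`.
#' @export
adjust_phenotypes <- function(pt, trait, method = c("animal_model", "fixed_only"),
                              grm = NULL, factors = c("farm", "sex", "batch")) {
  method <- match.arg(method)
  stopifnot(trait %in% names(pt), all(factors %in% names(pt)),
            "id" %in% names(pt))
  ok <- !is.na(pt[[trait]])
  pt <- pt[ok, , drop = FALSE]
  y <- pt[[trait]]
  n <- length(y)
  # drop factors with a single observed level (nothing to adjust)
  factors <- factors[vapply(factors, function(f)
    length(unique(pt[[f]])) > 1, logical(1))]
  if (length(factors) == 0) {
    yc <- setNames(y, pt$id)
    attr(yc, "beta") <- numeric(0)
    return(yc)
  }
  fml <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  X <- model.matrix(fml, data = pt)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confounded fixed effects; aliased levels: ",
         paste(aliased, collapse = ", "))
  }
  if (method == "fixed_only") {
    beta <- qr.coef(qx, y)
  } else {
    if (is.null(grm)) stop("animal_model requires a GRM")
    g <- subset_grm(grm, pt$id)
    fit <- reml_fit(setNames(y, pt$id), g, X = X)
    v <- fit$components
    V <- v[["g"]] * g$values + diag(v[["residual"]], n)
    Vi <- solve_spd(V)
    XtVi <- crossprod(X, Vi)
    beta <- drop(solve(XtVi %*% X, XtVi %*% y))
  }
  fittedX <- drop(X %*% beta)
  yc <- y - fittedX + mean(fittedX)
  yc <- setNames(yc, pt$id)
  attr(yc, "beta") <- beta
  yc
}

#' Per-trait summary statistics
#'
#' @param pt phenotype data.frame (column `id`, trait columns, optional
#'   factor columns which are skipped).
#' @param traits trait column names; default: all numeric columns.
#' @return data.frame (trait, n, mean, sd, min, max); missing values are
#'   excluded per trait, and degenerate traits (n < 2) report `NA` sd.
#' @export
summarize_traits <- function(pt, traits = NULL) {
  if (is.null(traits))
    traits <- names(pt)[vapply(pt, is.numeric, logical(1))]
  rows <- lapply(traits, function(tr) {
    x <- pt[[tr]]
    x <- x[!is.na(x)]
    data.frame(trait = tr, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2) sd(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
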