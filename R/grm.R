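#' Genomic relationship matrix
#'
#' Builds the additive genomic relationship matrix from dosages. The default
#' `vanraden1` algorithm centers each dosage column by twice its
#' alternate-allele frequency and uses a single shared denominator:
#' \deqn{G = \frac{M M^\top}{2\sum_i p_i(1-p_i)}}
#' (the first VanRaden construction, the GCTA `--make-grm-alg 1`
#' convention). `vanraden2` standardizes each marker to unit variance and
#' averages. Monomorphic columns are excluded; missing dosages are replaced
#' by `2 p_i` (zero after centering); `p_i` is estimated from the in-sample
#' non-missing dosages.
#'
#' @param gm a [geno_matrix()].
#' @param algorithm `"vanraden1"` (default) or `"vanraden2"`.
#' @return an object of class `grm`: list with `values` (symmetric n x n),
#'   `sample_ids`, `n_markers`, `algorithm`, `allele_freqs`.
#' @export
compute_grm <- function(gm, algorithm = c("vanraden1", "vanraden2")) {
  stopifnot(inherits(gm, "geno_matrix"))
  algorithm <- match.arg(algorithm)
  X <- gm$dosage
  p <- alt_freq(X)
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; GRM undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  W[is.na(W)] <- 0
  G <- if (algorithm == "vanraden1") {
    tcrossprod(W) / (2 * sum(p * (1 - p)))
  } else {
    Ws <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Ws) / length(p)
  }
  G <- (G + t(G)) / 2
  new_grm(G, rownames(X), length(p), algorithm, p)
}

new_grm <- function(values, ids, n_markers, algorithm, allele_freqs = NULL) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, sample_ids = ids,
                 n_markers = as.integer(n_markers), algorithm = algorithm,
                 allele_freqs = allele_freqs),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d markers, algorithm %s\n",
              length(x$sample_ids), x$n_markers, x$algorithm))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Subset a GRM to a set of samples
#' @param grm a `grm` object.
#' @param ids sample ids to keep (order respected).
#' @return a `grm` restricted to `ids`.
#' @export
subset_grm <- function(grm, ids) {
  stopifnot(inherits(grm, "grm"))
  i <- match(ids, grm$sample_ids)
  if (anyNA(i)) stop("unknown sample ids: ",
                     paste(ids[is.na(i)], collapse = ", "))
  new_grm(grm$values[i, i, drop = FALSE], grm$sample_ids[i],
          grm$n_markers, grm$algorithm, grm$allele_freqs)
}

#' Weighted average of relationship matrices
#'
#' Diagnostic utility: element-wise weighted mean of GRMs over a common
#' sample set (weights renormalized to sum to one). Multi-component models
#' keep their matrices separate; this is for comparisons only.
#'
#' @param grms list of `grm` objects with identical sample ids.
#' @param weights non-negative weights, sum > 0.
#' @return a combined `grm` (algorithm tag `"combined"`).
#' @export
combine_grms <- function(grms, weights) {
  stopifnot(length(grms) >= 1, length(weights) == length(grms),
            all(weights >= 0), sum(weights) > 0)
  ids <- grms[[1]]$sample_ids
  for (g in grms)
    if (!identical(g$sample_ids, ids)) stop("GRM sample ids do not match")
  w <- weights / sum(weights)
  V <- Reduce(`+`, Map(function(g, wi) g$values * wi, grms, w))
  new_grm(V, ids, sum(vapply(grms, `[[`, integer(1), "n_markers")),
          "combined")
}
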