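#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of the (VanRaden) GRM - numerically equivalent to PCA
#' of the centered, scaled genotypes. Components are ordered by eigenvalue;
#' each component's sign is fixed so its largest-magnitude loading is
#' positive. Explained-variance fractions are eigenvalues over the sum of
#' positive eigenvalues.
#'
#' @param x a [geno_matrix()] (a `vanraden1` GRM is built internally) or a
#'   `grm`.
#' @param n_components number of components requested; truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return list with `scores` (n x K, eigenvectors scaled by the square
#'   root of their eigenvalues), `eigenvalues`, `variance_fraction`.
#' @export
genotype_pca <- function(x, n_components = 10) {
  g <- if (inherits(x, "geno_matrix")) compute_grm(x) else x
  stopifnot(inherits(g, "grm"), n_components >= 1)
  n <- length(g$sample_ids)
  if (n < n_components + 1) stop("need n >= n_components + 1 samples")
  eg <- eigen(g$values, symmetric = TRUE)
  pos <- which(eg$values > 1e-10 * max(eg$values))
  K <- n_components
  if (length(pos) < K) {
    warning("only ", length(pos), " positive eigenvalues; truncating")
    K <- length(pos)
  }
  U <- eg$vectors[, seq_len(K), drop = FALSE]
  lam <- eg$values[seq_len(K)]
  for (j in seq_len(K)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  scores <- sweep(U, 2, sqrt(lam), `*`)
  dimnames(scores) <- list(g$sample_ids, paste0("PC", seq_len(K)))
  list(scores = scores, eigenvalues = lam,
       variance_fraction = lam / sum(eg$values[pos]))
}

#' Identity-by-state similarity matrix
#'
#' Pairwise IBS similarity `mean(1 - |x_i - x_j| / 2)` over variants
#' non-missing in both individuals; diagonal 1. Pairs sharing no non-missing
#' variant get `NA`.
#'
#' @param gm a [geno_matrix()] with at least one variant.
#' @return symmetric n x n matrix with entries in `[0, 1]`.
#' @export
ibs_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"), ncol(gm$dosage) >= 1)
  X <- gm$dosage
  m <- ncol(X)
  # dist() rescales partial sums by m / n_valid, so value/m is the mean
  # absolute dosage difference over the shared non-missing variants
  D <- as.matrix(dist(X, method = "manhattan"))
  S <- 1 - D / (2 * m)
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' LD decay curve
#'
#' Squared dosage correlation for all intra-chromosomal variant pairs
#' within `max_distance` base pairs (variants with MAF strictly above
#' `maf_min`), averaged in distance bins. Default bins are log-spaced up to
#' the maximum distance, which resolves the short-range decay.
#'
#' @param gm a [geno_matrix()] with chromosome/position metadata.
#' @param max_distance maximum pair distance in bp.
#' @param maf_min MAF filter (strict).
#' @param breaks optional distance-bin breakpoints; default 50 log-spaced
#'   bins.
#' @return data.frame (dist_low, dist_high, mean_r2, n_pairs); empty bins
#'   kept with `n_pairs = 0`.
#' @export
ld_decay <- function(gm, max_distance = 1e6, maf_min = 0.05, breaks = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  keep <- which(v$maf > maf_min)
  if (length(keep) < 2) stop("fewer than two variants pass the MAF filter")
  if (is.null(breaks)) {
    lo <- max(1, min(diff(sort(unique(v$pos)))))
    breaks <- exp(seq(log(lo), log(max_distance), length.out = 51))
  }
  nb <- length(breaks) - 1
  sums <- numeric(nb); counts <- integer(nb)
  for (chr in unique(v$chrom[keep])) {
    j <- keep[v$chrom[keep] == chr]
    if (length(j) < 2) next
    R2 <- suppressWarnings(cor(gm$dosage[, j, drop = FALSE],
                               use = "pairwise.complete.obs")^2)
    Dm <- abs(outer(v$pos[j], v$pos[j], `-`))
    ut <- upper.tri(R2)
    d <- Dm[ut]; r <- R2[ut]
    sel <- d <= max_distance & !is.na(r)
    b <- findInterval(d[sel], breaks, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= nb
    if (any(ok)) {
      agg <- tapply(r[sel][ok], b[ok], sum)
      cnt <- table(b[ok])
      i <- as.integer(names(agg))
      sums[i] <- sums[i] + as.numeric(agg)
      counts[i] <- counts[i] + as.integer(cnt)
    }
  }
  data.frame(dist_low = breaks[-length(breaks)], dist_high = breaks[-1],
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}

#' Euclidean phenotype distance
#'
#' Pairwise Euclidean distance over (optionally standardized) trait
#' vectors, computed on the traits non-missing in both individuals of a
#' pair. Pairs sharing no trait get `NA`.
#'
#' @param pt phenotype data.frame with an `id` column.
#' @param traits trait column names (default: all numeric columns).
#' @param standardize scale each trait to unit variance first.
#' @return symmetric n x n distance matrix, zero diagonal.
#' @export
pheno_distance <- function(pt, traits = NULL, standardize = TRUE) {
  if (is.null(traits))
    traits <- names(pt)[vapply(pt, is.numeric, logical(1))]
  X <- as.matrix(pt[, traits, drop = FALSE])
  if (standardize) X <- scale(X)
  V <- 1 * !is.na(X)
  X0 <- X; X0[is.na(X0)] <- 0
  S2 <- X0^2
  D2 <- S2 %*% t(V) + V %*% t(S2) - 2 * X0 %*% t(X0)
  shared <- V %*% t(V)
  D <- sqrt(pmax(D2, 0))
  D[shared == 0] <- NA
  diag(D) <- 0
  dimnames(D) <- list(pt$id, pt$id)
  D
}
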