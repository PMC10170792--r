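#' Call-rate / MAF quality control
#'
#' Retains variants with call rate strictly above `min_call_rate` and MAF
#' strictly above `min_maf` (both recomputed from the non-missing dosages).
#' The sample set is unchanged. A report of removed counts per criterion is
#' attached as attribute `"qc_report"`.
#'
#' @param gm a [geno_matrix()].
#' @param min_call_rate,min_maf thresholds in `[0, 1]` (strict inequalities).
#' @return a filtered `geno_matrix`; warns (and returns an empty matrix) if
#'   nothing survives.
#' @export
qc_filter <- function(gm, min_call_rate = 0.9, min_maf = 0.01) {
  stopifnot(inherits(gm, "geno_matrix"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  cr <- colMeans(!is.na(gm$dosage))
  maf <- variant_maf(gm$dosage)
  maf[is.na(maf)] <- 0
  pass_cr <- cr > min_call_rate
  pass_maf <- maf > min_maf
  keep <- pass_cr & pass_maf
  if (!any(keep)) warning("qc_filter removed every variant")
  out <- subset_geno(gm, variants = which(keep))
  attr(out, "qc_report") <- c(n_input = length(keep),
                              removed_call_rate = sum(!pass_cr),
                              removed_maf = sum(!pass_maf),
                              n_kept = sum(keep))
  out
}

#' Random density thinning of a variant panel
#'
#' Two modes mirror common tooling: `bernoulli` keeps each variant
#' independently with the given probability (the semantics of a
#' `--thin`-style fraction), `exact` draws a uniform subset of exactly the
#' requested count, which makes the 1K/3K/.../10,000K panel sizes of a
#' density sweep deterministic. Genomic order is preserved.
#'
#' @param gm a [geno_matrix()] or a [as_variant_panel()] data.frame.
#' @param mode `"exact"` or `"bernoulli"`.
#' @param fraction keep probability for bernoulli mode, in `(0, 1]`.
#' @param count subset size for exact mode.
#' @param seed integer seed.
#' @return a `variant_panel` (subset of the input, original order).
#' @export
thin_variants <- function(gm, mode = c("exact", "bernoulli"),
                          fraction = NULL, count = NULL, seed = 1) {
  mode <- match.arg(mode)
  panel <- if (inherits(gm, "geno_matrix")) gm$variants else as_variant_panel(gm)
  m <- nrow(panel)
  withr::with_seed(as.integer(seed), {
    keep <- if (mode == "bernoulli") {
      stopifnot(!is.null(fraction), fraction > 0, fraction <= 1)
      which(runif(m) < fraction)
    } else {
      stopifnot(!is.null(count), count >= 1)
      if (count > m) stop("requested count ", count, " exceeds ", m, " variants")
      sort(sample.int(m, count))
    }
    as_variant_panel(panel[keep, , drop = FALSE])
  })
}

#' Sliding-window LD pruning
#'
#' PLINK-style `indep-pairwise` pruning: windows of `window` variants
#' advanced by `step`, per chromosome. Within a window, while any retained
#' pair has squared dosage correlation at or above `r2_threshold`, one
#' member is removed: the variant with the lower MAF, or on equal MAF the
#' later-positioned one. Pairs are scanned in position order and r2 is
#' computed on samples non-missing at both variants (composite LD).
#' Monomorphic variants have undefined r2; they are skipped in pair tests
#' but retained. Full passes are repeated until no removal occurs, so the
#' result is a fixpoint: re-pruning it removes nothing.
#'
#' @param gm a [geno_matrix()].
#' @param window window size in variants (>= 2).
#' @param step window advance in variants.
#' @param r2_threshold pruning threshold in `(0, 1]`.
#' @return a `variant_panel` of retained variants (genomic order).
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_threshold = 0.6) {
  stopifnot(inherits(gm, "geno_matrix"), window >= 2, step >= 1,
            r2_threshold > 0, r2_threshold <= 1)
  X <- gm$dosage
  v <- gm$variants
  keep <- rep(TRUE, ncol(X))
  prune_window <- function(idx) {
    # greedy removal inside one window; returns ids removed this call
    repeat {
      act <- idx[keep[idx]]
      if (length(act) < 2) return(invisible(NULL))
      r2 <- suppressWarnings(cor(X[, act, drop = FALSE],
                                 use = "pairwise.complete.obs")^2)
      viol <- which(upper.tri(r2) & !is.na(r2) & r2 >= r2_threshold,
                    arr.ind = TRUE)
      if (nrow(viol) == 0) return(invisible(NULL))
      # first violating pair in scan order (columns vary fastest => order rows)
      o <- order(viol[, 2], viol[, 1])[1]
      i <- act[viol[o, 1]]; j <- act[viol[o, 2]]
      drop <- if (v$maf[i] < v$maf[j]) i
              else if (v$maf[j] < v$maf[i]) j
              else j                      # equal MAF: later-positioned
      keep[drop] <<- FALSE
    }
  }
  for (chr in unique(v$chrom)) {
    idx_all <- which(v$chrom == chr)
    repeat {
      before <- sum(keep[idx_all])
      cur <- idx_all[keep[idx_all]]
      if (length(cur) >= 2) {
        start <- 1
        repeat {
          win <- cur[start:min(start + window - 1, length(cur))]
          prune_window(win)
          if (start + window - 1 >= length(cur)) break
          start <- start + step
        }
      }
      if (sum(keep[idx_all]) == before) break   # pass made no removal
    }
  }
  as_variant_panel(v[keep, , drop = FALSE])
}

#' Intersect two variant panels
#'
#' Variants are matched on the `(chromosome, position, ref, alt)` key; the
#' output keeps the order of `a`. Counts of shared variants are reported per
#' type as attribute `"intersect_report"`.
#'
#' @param a,b `variant_panel` data.frames.
#' @return the shared variants, ordered as in `a`.
#' @export
intersect_panels <- function(a, b) {
  a <- as_variant_panel(a); b <- as_variant_panel(b)
  key <- function(p) paste(p$chrom, p$pos, p$ref, p$alt, sep = ":")
  ka <- key(a); kb <- key(b)
  for (nm in c("a", "b")) {
    k <- if (nm == "a") ka else kb
    if (anyDuplicated(k))
      stop("duplicate (chrom,pos,ref,alt) keys in panel ", nm, ": ",
           paste(unique(k[duplicated(k)]), collapse = ", "))
  }
  out <- a[ka %in% kb, , drop = FALSE]
  rep_ <- c(n_shared = nrow(out),
            n_snp = sum(out$type == "SNP"),
            n_indel = sum(out$type == "INDEL"))
  out <- as_variant_panel(out)
  attr(out, "intersect_report") <- rep_
  out
}
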