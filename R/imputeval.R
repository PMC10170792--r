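#' Per-variant genotype concordance
#'
#' Fraction of exactly matching hard calls between an observed (truth) and
#' an imputed genotype matrix, per variant, among pairs where the observed
#' call is non-missing (a missing imputed call counts as a mismatch).
#'
#' @param observed,imputed [geno_matrix()] objects; matched on shared
#'   sample and variant ids.
#' @return data.frame (variant_id, maf, concordance, n_compared); variants
#'   with no comparable pair get `NA` concordance.
#' @export
concordance <- function(observed, imputed) {
  al <- align_pair(observed, imputed)
  O <- al$O; I <- al$I
  ok <- !is.na(O)
  match_ <- !is.na(I) & I == O
  match_[!ok] <- FALSE
  n_cmp <- colSums(ok)
  cr <- ifelse(n_cmp > 0, colSums(match_) / n_cmp, NA_real_)
  data.frame(variant_id = colnames(O), maf = al$maf,
             concordance = cr, n_compared = n_cmp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-variant dosage r-squared
#'
#' Squared Pearson correlation between observed and imputed dosages per
#' variant, over pairs non-missing on both sides. Undefined (and excluded
#' from downstream means) when fewer than 3 pairs remain or either side has
#' zero variance.
#'
#' @inheritParams concordance
#' @return data.frame (variant_id, maf, r2, n_compared).
#' @export
dosage_r2 <- function(observed, imputed) {
  al <- align_pair(observed, imputed)
  O <- al$O; I <- al$I
  r2 <- vapply(seq_len(ncol(O)), function(j) {
    ok <- !is.na(O[, j]) & !is.na(I[, j])
    if (sum(ok) < 3) return(NA_real_)
    x <- O[ok, j]; g <- I[ok, j]
    vx <- var(x); vg <- var(g)
    if (vx == 0 || vg == 0) return(NA_real_)
    cov(x, g)^2 / (vx * vg)   # == cor^2, exact 1 on identical vectors
  }, numeric(1))
  n_cmp <- colSums(!is.na(O) & !is.na(I))
  data.frame(variant_id = colnames(O), maf = al$maf, r2 = r2,
             n_compared = n_cmp, stringsAsFactors = FALSE, row.names = NULL)
}

align_pair <- function(observed, imputed) {
  stopifnot(inherits(observed, "geno_matrix"), inherits(imputed, "geno_matrix"))
  sids <- intersect(sample_ids(observed), sample_ids(imputed))
  vids <- intersect(observed$variants$variant_id, imputed$variants$variant_id)
  if (length(sids) == 0 || length(vids) == 0)
    stop("no overlapping samples/variants between the two matrices")
  O <- observed$dosage[sids, vids, drop = FALSE]
  I <- imputed$dosage[sids, vids, drop = FALSE]
  maf <- observed$variants$maf[match(vids, observed$variants$variant_id)]
  list(O = O, I = I, maf = maf)
}

#' Bin per-variant statistics by MAF
#'
#' Half-open bins `[k w, (k+1) w)` of width `bin_width` covering
#' `[0, 0.5]`, the last bin closed. Empty bins are present with count 0.
#' Bin means equal the mean of member per-variant values (variants with
#' undefined statistics excluded, counts reported).
#'
#' @param per_variant data.frame with `maf` plus any of `concordance`,
#'   `r2`.
#' @param bin_width bin width (default 0.01, i.e. 50 bins).
#' @return data.frame (maf_bin_low, maf_bin_high, n_variants,
#'   mean_concordance and/or mean_r2 with their defined-variant counts).
#' @export
bin_by_maf <- function(per_variant, bin_width = 0.01) {
  stopifnot("maf" %in% names(per_variant), bin_width > 0, bin_width <= 0.5)
  breaks <- seq(0, 0.5, by = bin_width)
  if (tail(breaks, 1) < 0.5) breaks <- c(breaks, 0.5)
  nb <- length(breaks) - 1
  bin <- findInterval(per_variant$maf, breaks, rightmost.closed = TRUE)
  bin[bin < 1 | bin > nb] <- NA
  out <- data.frame(maf_bin_low = breaks[-length(breaks)],
                    maf_bin_high = breaks[-1])
  out$n_variants <- vapply(seq_len(nb), function(b)
    sum(!is.na(bin) & bin == b), integer(1))
  for (stat in intersect(c("concordance", "r2"), names(per_variant))) {
    x <- per_variant[[stat]]
    out[[paste0("mean_", stat)]] <- vapply(seq_len(nb), function(b) {
      v <- x[!is.na(bin) & bin == b]
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out[[paste0("n_", stat)]] <- vapply(seq_len(nb), function(b)
      sum(!is.na(x[!is.na(bin) & bin == b])), integer(1))
  }
  out
}

#' Imputation accuracy report
#'
#' Combines [concordance()] and [dosage_r2()] per variant, bins them by MAF
#' ([bin_by_maf()]) and summarises genome-wide. The overall values are the
#' unweighted means over variants with a defined statistic (the per-variant
#' averaging convention); a call-weighted overall concordance (total
#' correct / total compared) is also reported.
#'
#' @inheritParams concordance
#' @param bin_width MAF bin width.
#' @return object of class `impute_accuracy`: `per_variant`, `bins`,
#'   `overall_concordance`, `overall_r2`, `overall_concordance_weighted`,
#'   `n_variants`, `n_undefined` counts.
#' @export
impute_accuracy <- function(observed, imputed, bin_width = 0.01) {
  cr <- concordance(observed, imputed)
  r2 <- dosage_r2(observed, imputed)
  pv <- merge(cr, r2[, c("variant_id", "r2")], by = "variant_id", sort = FALSE)
  bins <- bin_by_maf(pv, bin_width)
  structure(list(
    per_variant = pv,
    bins = bins,
    overall_concordance = mean(pv$concordance, na.rm = TRUE),
    overall_r2 = mean(pv$r2, na.rm = TRUE),
    overall_concordance_weighted =
      sum(pv$concordance * pv$n_compared, na.rm = TRUE) /
      sum(pv$n_compared[!is.na(pv$concordance)]),
    n_variants = nrow(pv),
    n_undefined = c(concordance = sum(is.na(pv$concordance)),
                    r2 = sum(is.na(pv$r2)))),
    class = "impute_accuracy")
}

#' @export
print.impute_accuracy <- function(x, ...) {
  cat(sprintf("imputation accuracy over %d variants\n", x$n_variants))
  cat(sprintf("  overall concordance %.4f (call-weighted %.4f); overall r2 %.4f\n",
              x$overall_concordance, x$overall_concordance_weighted,
              x$overall_r2))
  cat(sprintf("  undefined: %d concordance, %d r2\n",
              x$n_undefined[["concordance"]], x$n_undefined[["r2"]]))
  invisible(x)
}

#' @describeIn impute_accuracy two-panel summary plot: concordance and r2
#'   against MAF-bin midpoint, plus the variant-count histogram.
#' @param x an `impute_accuracy` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.impute_accuracy <- function(x, ...) {
  b <- x$bins[x$bins$n_variants > 0, ]
  mid <- (b$maf_bin_low + b$maf_bin_high) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(mid, b$mean_concordance, type = "b", pch = 16,
                 xlab = "MAF bin midpoint", ylab = "accuracy",
                 ylim = range(c(b$mean_concordance, b$mean_r2), na.rm = TRUE),
                 ...)
  graphics::lines(mid, b$mean_r2, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomleft", legend = c("concordance", "r2"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  graphics::barplot(b$n_variants, names.arg = round(mid, 2),
                    xlab = "MAF bin", ylab = "variants")
  invisible(x)
}
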