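#' Genotype matrix container
#'
#' Bundles an individuals-by-variants dosage matrix (counts of the alternate
#' allele, in `{0, 1, 2, NA}`) with per-variant metadata. Minor-allele
#' frequency and call rate are computed from the non-missing dosages and
#' cached on the variant table.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names are sample ids, column names
#'   variant ids; defaults are generated when absent.
#' @param variants data.frame with one row per variant. Recognised columns:
#'   `variant_id`, `chrom`, `pos`, `type` (`"SNP"` or `"INDEL"`), `ref`,
#'   `alt`. Missing columns are filled with defaults.
#' @param subpop optional per-sample subpopulation labels (length = rows).
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `variants` (a [variant_panel()] data.frame with cached `maf` and
#'   `call_rate`) and optional `subpop`.
#' @export
geno_matrix <- function(dosage, variants = NULL, subpop = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosage entries must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "double"
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind%04d", seq_len(n))
  if (is.null(variants)) {
    variants <- data.frame(
      variant_id = colnames(dosage) %||% sprintf("var%06d", seq_len(m)),
      chrom = 1L, pos = seq_len(m), type = "SNP", ref = "A", alt = "C",
      stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != m)
    stop("variants table has ", nrow(variants), " rows but dosage has ", m,
         " columns")
  if (is.null(variants$variant_id))
    variants$variant_id <- colnames(dosage) %||% sprintf("var%06d", seq_len(m))
  if (is.null(variants$chrom)) variants$chrom <- 1L
  if (is.null(variants$pos))   variants$pos <- seq_len(m)
  if (is.null(variants$type))  variants$type <- "SNP"
  if (is.null(variants$ref))   variants$ref <- "A"
  if (is.null(variants$alt))   variants$alt <- ifelse(variants$type == "INDEL", "AC", "C")
  colnames(dosage) <- variants$variant_id
  variants$maf <- variant_maf(dosage)
  variants$call_rate <- colMeans(!is.na(dosage))
  if (!is.null(subpop) && length(subpop) != n)
    stop("subpop must have one label per sample")
  structure(list(dosage = dosage,
                 variants = as_variant_panel(variants),
                 subpop = subpop),
            class = "geno_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%d SNP, %d INDEL)\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$variants$type == "SNP"), sum(x$variants$type == "INDEL")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Sample identifiers of a genotype matrix or GRM
#' @param x a `geno_matrix` or `grm` object.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "geno_matrix")) rownames(x$dosage)
  else if (inherits(x, "grm")) x$sample_ids
  else stop("no sample ids for class ", paste(class(x), collapse = "/"))
}

# alternate-allele frequency per variant, from non-missing dosages
alt_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

variant_maf <- function(dosage) {
  p <- alt_freq(dosage)
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Variant panel
#'
#' Validates a table of variants: unique ids and MAF in `[0, 0.5]`.
#' Panels produced by the generators and panel operations are ordered by
#' position within chromosome; explicit reordering (e.g. of matrix columns)
#' is permitted.
#'
#' @param x data.frame with at least `variant_id`; typically also `chrom`,
#'   `pos`, `type`, `ref`, `alt`, `maf`, `call_rate`.
#' @return `x` with class `c("variant_panel", "data.frame")`.
#' @export
as_variant_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (anyDuplicated(x$variant_id))
    stop("duplicate variant ids: ",
         paste(unique(x$variant_id[duplicated(x$variant_id)]), collapse = ", "))
  if (!is.null(x$maf) && any(x$maf < -1e-12 | x$maf > 0.5 + 1e-12, na.rm = TRUE))
    stop("maf outside [0, 0.5]")
  class(x) <- c("variant_panel", "data.frame")
  x
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param samples sample ids (or logical/integer index) to keep; default all.
#' @param variants variant ids (or logical/integer index) to keep; default
#'   all. Order of the selection is preserved.
#' @return a new `geno_matrix` (maf/call_rate recomputed on the subset).
#' @export
subset_geno <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(gm$dosage)) else samples
  if (is.character(si)) si <- match(si, rownames(gm$dosage))
  if (anyNA(si)) stop("unknown sample ids in subset")
  vi <- if (is.null(variants)) seq_len(ncol(gm$dosage)) else variants
  if (is.character(vi)) vi <- match(vi, gm$variants$variant_id)
  if (anyNA(vi)) stop("unknown variant ids in subset")
  geno_matrix(gm$dosage[si, vi, drop = FALSE],
              gm$variants[vi, setdiff(names(gm$variants), c("maf", "call_rate")),
                          drop = FALSE],
              subpop = gm$subpop[si])
}
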