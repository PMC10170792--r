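#' Write genotypes as a minimal VCF
#'
#' One biallelic record per variant; the `VT` INFO tag distinguishes SNP
#' and INDEL records and genotypes are unphased hard calls (`0/0`, `0/1`,
#' `1/1`, `./.`).
#'
#' @param gm a [geno_matrix()].
#' @param path output file (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  X <- gm$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[X + 1], nrow(X), ncol(X))
  gt[is.na(X)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wgsblup",
    '##INFO=<ID=VT,Number=1,Type=String,Description="Variant type (SNP or INDEL)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(X)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                paste0("VT=", v$type), "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Parsing is delegated to `VariantAnnotation::readVcf`; genotypes are
#' converted to alternate-allele dosages and variants classified as SNP or
#' INDEL by comparing allele lengths.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
           "1|0" = 1, "1/1" = 2, "1|1" = 2)
  dos <- matrix(unname(map[gt]), nrow(gt), ncol(gt))
  dos <- t(dos)   # samples x variants
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  variants <- data.frame(
    variant_id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    type = ifelse(nchar(ref) != nchar(alt), "INDEL", "SNP"),
    ref = ref, alt = alt, stringsAsFactors = FALSE)
  rownames(dos) <- colnames(gt)
  geno_matrix(dos, variants)
}

#' Write / read the plain-text dosage dialect
#'
#' Tab-separated text: header row `id` followed by variant ids, then one
#' row per sample with dosages (`NA` for missing).
#'
#' @param gm a [geno_matrix()].
#' @param path file path.
#' @return `write_dosage`: `path` invisibly; `read_dosage`: a
#'   [geno_matrix()] (variant metadata from `panel` when given, minimal
#'   defaults otherwise).
#' @export
write_dosage <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  dt <- data.table::data.table(id = rownames(gm$dosage))
  dt <- cbind(dt, data.table::as.data.table(gm$dosage))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @param panel optional variant table (e.g. from [write_panel()]) supplying
#'   chrom/pos/type/ref/alt for the dosage columns.
#' @export
read_dosage <- function(path, panel = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "id"))
  ids <- dt$id
  X <- as.matrix(dt[, -1])
  rownames(X) <- ids
  variants <- NULL
  if (!is.null(panel)) {
    if (is.character(panel)) panel <- read_panel(panel)
    variants <- panel[match(colnames(X), panel$variant_id), , drop = FALSE]
    variants <- variants[, setdiff(names(variants), c("maf", "call_rate")),
                         drop = FALSE]
    if (anyNA(variants$variant_id))
      stop("panel does not cover all dosage columns")
  }
  geno_matrix(X, variants)
}

#' Write / read a variant panel
#'
#' @param panel a `variant_panel` data.frame.
#' @param path file path.
#' @param ids_only write only the variant ids, one per line.
#' @return `write_panel`: `path` invisibly; `read_panel`: a
#'   `variant_panel` (or character ids when the file has a single unnamed
#'   column).
#' @export
write_panel <- function(panel, path, ids_only = FALSE) {
  if (ids_only) writeLines(panel$variant_id, path)
  else data.table::fwrite(as.data.frame(panel), path, sep = "\t",
                          quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("\t", first)) return(readLines(path))
  as_variant_panel(as.data.frame(data.table::fread(path, sep = "\t")))
}

#' Write / read phenotype tables
#'
#' Tab-separated with header: `id`, trait columns, factor columns.
#'
#' @param pt phenotype data.frame.
#' @param path file path.
#' @return `write_pheno`: `path` invisibly; `read_pheno`: data.frame with
#'   character `id` and factor-coded non-numeric columns.
#' @export
write_pheno <- function(pt, path) {
  data.table::fwrite(pt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "id")))
  for (j in setdiff(names(dt), "id"))
    if (is.character(dt[[j]])) dt[[j]] <- factor(dt[[j]])
  dt
}

#' GRM binary triplet I/O (GCTA layout)
#'
#' Writes/reads the three-file binary layout used by common GREML tooling:
#' `<prefix>.grm.bin` - the lower triangle (including the diagonal), row by
#' row, as little-endian 4-byte floats; `<prefix>.grm.N.bin` - the marker
#' count per pair in the same layout; `<prefix>.grm.id` - tab-separated
#' family and individual id columns.
#'
#' @param grm a `grm` object.
#' @param prefix path prefix for the triplet.
#' @return `write_grm`: `prefix` invisibly; `read_grm`: a `grm`.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  # stored row-by-row lower triangle; for a symmetric matrix that equals
  # the column-wise upper triangle, which is R's upper.tri order
  lt <- grm$values[upper.tri(grm$values, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_markers), length(lt)), con, size = 4,
           endian = "little")
  close(con)
  write.table(data.frame(grm$sample_ids, grm$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), sep = "\t",
                    stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  n_lt <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lt <- readBin(con, "numeric", n = n_lt, size = 4, endian = "little")
  close(con)
  Nf <- paste0(prefix, ".grm.N.bin")
  n_markers <- if (file.exists(Nf)) {
    con <- file(Nf, "rb")
    nm <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
    close(con)
    as.integer(round(nm))
  } else NA_integer_
  V <- matrix(0, n, n)
  V[upper.tri(V, diag = TRUE)] <- lt
  V <- V + t(V) - diag(diag(V))
  new_grm(V, ids, n_markers, "vanraden1")
}

#' Write a GRM as plain-text lower triangle
#'
#' Four tab-separated columns per pair `(i, j <= i)`: the two 1-based
#' sample indices, the marker count, and the relationship value.
#'
#' @param grm a `grm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grm_text <- function(grm, path) {
  n <- length(grm$sample_ids)
  idx <- which(upper.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  # (row <= col) pairs of the upper triangle == row-wise lower triangle
  out <- data.frame(i = idx[, 2], j = idx[, 1],
                    n_markers = grm$n_markers,
                    value = grm$values[idx])
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' Compact reader for the SNP-major PLINK 1 binary layout (magic bytes
#' `0x6c 0x1b 0x01`, two bits per genotype). Dosages count the A1 allele
#' of the `.bim` file.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return a [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- as.data.frame(data.table::fread(paste0(prefix, ".bim"),
                                         header = FALSE))
  names(bim) <- c("chrom", "variant_id", "cm", "pos", "a1", "a2")
  fam <- as.data.frame(data.table::fread(paste0(prefix, ".fam"),
                                         header = FALSE))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  raw <- raw[-(1:3)]
  # 2-bit codes per sample: 00 hom A1 (dosage 2), 01 missing, 10 het, 11 hom A2
  codes <- c(2, NA, 1, 0)
  lookup <- t(vapply(0:255, function(b)
    codes[1 + c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))],
    numeric(4)))
  bpv <- ceiling(n / 4)
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(raw[((j - 1) * bpv + 1):(j * bpv)])
    g <- as.vector(t(lookup[bytes + 1, , drop = FALSE]))
    dos[, j] <- g[seq_len(n)]
  }
  rownames(dos) <- as.character(fam[[2]])
  variants <- data.frame(variant_id = bim$variant_id, chrom = bim$chrom,
                         pos = bim$pos,
                         type = ifelse(nchar(bim$a1) != nchar(bim$a2),
                                       "INDEL", "SNP"),
                         ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE)
  geno_matrix(dos, variants)
}
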