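#' Write a dosage matrix as TSV
#'
#' Samples by SNPs, header row of SNP IDs, first column `sample_id`.
#'
#' @param Z Dosage matrix.
#' @param path Output file.
#' @param sample_ids Row identifiers; defaults to rownames or `s1..sn`.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(Z, path, sample_ids = NULL) {
  Z <- as.matrix(Z)
  if (is.null(sample_ids))
    sample_ids <- rownames(Z) %||% paste0("s", seq_len(nrow(Z)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("snp", seq_len(ncol(Z)))
  df <- data.frame(sample_id = sample_ids, Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype dosage matrix from TSV or VCF
#'
#' TSV: samples x SNPs with a `sample_id` first column (the format written
#' by [write_dosage_tsv()]).  VCF: diploid GT fields are converted to
#' additive dosage (count of ALT alleles); multi-allelic sites are
#' rejected, and variants with missing genotypes (`./.`) are excluded with
#' a warning.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A numeric matrix (samples x SNPs) with sample IDs as rownames.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE)
    if (ncol(df) < 2 || names(df)[1] != "sample_id")
      vclrt_stop(sprintf("%s: expected a 'sample_id' first column", path),
                 "vclrt_parse_error")
    Z <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!stats::complete.cases(Z) | apply(Z, 1, function(r) any(!is.finite(r))))
    if (length(bad))
      vclrt_stop(sprintf("%s: malformed dosage rows at lines %s", path,
                         paste(bad + 1L, collapse = ", ")),
                 "vclrt_parse_error")
    storage.mode(Z) <- "double"
    rownames(Z) <- as.character(df$sample_id)
    return(Z)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    vclrt_stop(sprintf("%s: multi-allelic sites are not supported (rows %s)",
                       path, paste(which(grepl(",", alt)), collapse = ", ")),
               "vclrt_parse_error")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | grepl("\\.", g), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  miss <- apply(dos, 1, anyNA)
  if (any(miss)) {
    vclrt_warn(sprintf("%s: excluded %d variant(s) with missing genotypes",
                       path, sum(miss)), "vclrt_missing_genotypes")
    dos <- dos[!miss, , drop = FALSE]
  }
  Z <- t(dos)
  storage.mode(Z) <- "double"
  Z
}

#' Export a dosage matrix as a minimal VCF
#'
#' Dosages 0/1/2 become unphased diploid genotypes `0/0`, `0/1`, `1/1`.
#' Intended for round-trip interchange of simulated genotypes.
#'
#' @param Z Dosage matrix with entries in `{0, 1, 2}`.
#' @param path Output file (plain-text `.vcf`).
#' @param chrom Chromosome label for all sites.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(Z, path, chrom = "1") {
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1, 2)))
    vclrt_stop("VCF export needs dosages in {0, 1, 2}", "vclrt_invalid_input")
  ids <- rownames(Z) %||% paste0("s", seq_len(nrow(Z)))
  snps <- colnames(Z) %||% paste0("snp", seq_len(ncol(Z)))
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", chrom),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(Z)), function(k) {
    paste(c(chrom, k, snps[k], "A", "G", ".", "PASS", ".", "GT",
            gt_codes[Z[, k] + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phenotypes and covariates from TSV
#'
#' Expected columns: `sample_id`, a binary response column `y`, and any
#' further numeric columns treated as covariates (an intercept column is
#' prepended).
#'
#' @param path Input TSV file.
#' @return A list with `y`, `X` (intercept + covariates) and `ids`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("sample_id", "y") %in% names(df)))
    vclrt_stop(sprintf("%s: need 'sample_id' and 'y' columns", path),
               "vclrt_parse_error")
  y <- df$y
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    vclrt_stop(sprintf("%s: non-binary phenotype at lines %s", path,
                       paste(bad + 1L, collapse = ", ")), "vclrt_parse_error")
  covars <- df[, setdiff(names(df), c("sample_id", "y")), drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(covars))
  list(y = as.numeric(y), X = X, ids = as.character(df$sample_id))
}

#' Assemble a design from genotype and phenotype files
#'
#' Matches samples by the intersection of genotype and phenotype IDs
#' (order-aligned to the phenotype file after intersection).
#'
#' @param genotypes Dosage matrix with sample rownames
#'   (see [read_genotypes()]).
#' @param phenotypes A list from [read_phenotypes()].
#' @return A [design_data()] object.
#' @export
build_design <- function(genotypes, phenotypes) {
  ids <- intersect(phenotypes$ids, rownames(genotypes))
  if (length(ids) == 0)
    vclrt_stop("no overlapping sample IDs between genotypes and phenotypes",
               "vclrt_parse_error")
  pi <- match(ids, phenotypes$ids)
  design_data(phenotypes$y[pi], phenotypes$X[pi, , drop = FALSE],
              genotypes[ids, , drop = FALSE])
}
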