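#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only, converts
#' GT fields to allele-dosage codes (phase is ignored, so `0|1` and `0/1`
#' both become 1; half-missing calls such as `./1` become missing), and
#' applies minor-allele-frequency and missingness filters.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param min_maf Minimum minor allele frequency; loci with MAF below this
#'   are dropped. Must be in `[0, 0.5)`. Default 0.05, the usual
#'   genotyping-pipeline cutoff.
#' @param max_missing Maximum fraction of missing calls per locus; default 1
#'   (no missingness filter).
#' @param verbose Log a line per skipped record class. Default `TRUE`.
#'
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, min_maf = 0.05, max_missing = 1, verbose = TRUE) {
  stopifnot(min_maf >= 0, min_maf < 0.5, max_missing >= 0, max_missing <= 1)
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (verbose && n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s) (multi-allelic or indel)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (nrow(gt) == 0L) {
    stop("empty matrix: no biallelic SNP records in ", path)
  }
  calls <- t(gt_to_code(gt))  # samples x loci
  loci <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, loci, samples = colnames(gt))
  filter_loci(gm, min_maf = min_maf, max_missing = max_missing,
              verbose = verbose)
}

# GT strings -> dosage codes; anything other than two called alleles -> NA
gt_to_code <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- suppressWarnings(as.integer(a1) + as.integer(a2))
  code[!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))] <- NA_integer_
  dim(code) <- dim(gt)
  dimnames(code) <- dimnames(gt)
  code
}

#' Filter loci on minor allele frequency and missingness
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf Minimum minor allele frequency (loci with `MAF < min_maf`
#'   are removed; a monomorphic locus has MAF 0).
#' @param max_missing Maximum per-locus missing-call fraction.
#' @param verbose Log how many loci each filter removed.
#' @return A filtered `genotype_matrix`; errors if no locus survives.
#' @export
filter_loci <- function(gm, min_maf = 0, max_missing = 1, verbose = TRUE) {
  maf <- locus_maf(gm)
  miss <- colMeans(is.na(gm$calls))
  maf[is.nan(maf)] <- 0
  keep <- maf >= min_maf & miss <= max_missing
  if (verbose && any(!keep)) {
    message("filter_loci: removed ", sum(!keep), " of ", length(keep),
            " loci (MAF < ", min_maf, " or missingness > ", max_missing, ")")
  }
  if (!any(keep)) {
    stop("empty matrix: no loci survive filters (min_maf = ", min_maf,
         ", max_missing = ", max_missing, ")")
  }
  subset_loci(gm, which(keep))
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a GT-only VCF (unphased `0/0`, `0/1`, `1/1`, `./.`). Reading the
#' file back with [read_vcf()] (with filters off) reproduces the matrix
#' exactly.
#'
#' @param gm A non-empty [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  if (n_samples(gm) == 0L || n_loci(gm) == 0L) {
    stop("cannot write an empty genotype matrix")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=invscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_str <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
  gt_str[is.na(gt_str)] <- "./."
  dim(gt_str) <- dim(gm$calls)
  id <- gm$loci$id
  id[is.na(id) | id == ""] <- "."
  body <- paste(
    gm$loci$chrom, gm$loci$pos, id, gm$loci$ref, gm$loci$alt,
    ".", "PASS", ".", "GT",
    apply(gt_str, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}
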