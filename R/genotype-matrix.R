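#' Construct a genotype matrix
#'
#' The central container of the package: unphased diploid genotypes at
#' biallelic SNPs, coded as the count of the alternate allele
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing call).
#'
#' @param calls Integer matrix, samples in rows and loci in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param loci Data frame with one row per locus and columns `chrom`
#'   (character), `pos` (1-based physical position in bp), `id` (variant
#'   name, may be `NA`), `ref` and `alt` (single-character alleles).
#' @param samples Character vector of sample identifiers; defaults to the
#'   row names of `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix with sample row names), `loci` (data frame) and
#'   `samples` (character vector).
#'
#' @details Loci must be strictly sorted by position within each chromosome
#'   and chromosome blocks must be contiguous. Positions are 1-based
#'   inclusive throughout the package (VCF convention).
#'
#' @examples
#' gm <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 3),
#'   loci = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                     id = NA, ref = "A", alt = "G"),
#'   samples = c("s1", "s2", "s3")
#' )
#' n_loci(gm)
#' @export
genotype_matrix <- function(calls, loci, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(calls)))
  stopifnot(
    length(samples) == nrow(calls),
    is.data.frame(loci),
    all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
    nrow(loci) == ncol(calls)
  )
  if (!"id" %in% names(loci)) loci$id <- NA_character_
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$id <- as.character(loci$id)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  rownames(loci) <- NULL
  loci <- loci[, c("chrom", "pos", "id", "ref", "alt")]
  rownames(calls) <- samples
  colnames(calls) <- locus_key(loci)
  gm <- structure(
    list(calls = calls, loci = loci, samples = as.character(samples)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

locus_key <- function(loci) paste0(loci$chrom, ":", loci$pos)

validate_genotype_matrix <- function(gm) {
  bad <- !(gm$calls %in% c(0L, 1L, 2L) | is.na(gm$calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(gm$loci$pos < 1L)) stop("locus positions must be >= 1")
  if (any(gm$loci$ref == gm$loci$alt)) stop("ref and alt alleles must differ")
  for (ch in unique(gm$loci$chrom)) {
    p <- gm$loci$pos[gm$loci$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("loci on chromosome ", ch, " are not strictly sorted by position")
    }
  }
  # chromosome blocks contiguous: each chrom appears in exactly one run
  r <- rle(gm$loci$chrom)$values
  if (anyDuplicated(r)) stop("chromosome blocks are not contiguous")
  invisible(gm)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci on %d chromosome(s); %.2f%% missing\n",
    n_samples(x), n_loci(x), length(unique(x$loci$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' Per-locus minor allele frequency
#'
#' Computed from non-missing calls only: the alternate-allele frequency is
#' folded onto `[0, 0.5]`.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector, one MAF per locus (`NaN` for loci with no calls).
#' @export
locus_maf <- function(gm) {
  p <- colMeans(gm$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Subset a genotype matrix to a genomic region
#'
#' Returns the loci with position in the closed interval `[start, end]` on
#' `chrom`, preserving sample order. An empty region yields an empty matrix,
#' not an error.
#'
#' @param gm A `genotype_matrix`.
#' @param chrom Chromosome identifier.
#' @param start,end Region bounds in bp, 1-based inclusive; `start <= end`.
#' @return A `genotype_matrix` restricted to the region.
#' @export
subset_region <- function(gm, chrom, start, end) {
  stopifnot(start <= end)
  if (!chrom %in% gm$loci$chrom) {
    stop("unknown chromosome '", chrom, "'; available: ",
         paste(unique(gm$loci$chrom), collapse = ", "))
  }
  keep <- gm$loci$chrom == chrom & gm$loci$pos >= start & gm$loci$pos <= end
  subset_loci(gm, which(keep))
}

# index-based subsetting shared by filters and windows
subset_loci <- function(gm, idx) {
  structure(
    list(
      calls = gm$calls[, idx, drop = FALSE],
      loci = gm$loci[idx, , drop = FALSE],
      samples = gm$samples
    ),
    class = "genotype_matrix"
  )
}

subset_samples <- function(gm, samples) {
  idx <- if (is.character(samples)) match(samples, gm$samples) else samples
  structure(
    list(
      calls = gm$calls[idx, , drop = FALSE],
      loci = gm$loci,
      samples = gm$samples[idx]
    ),
    class = "genotype_matrix"
  )
}
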