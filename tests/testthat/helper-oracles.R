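# Independent oracles and small data builders shared across tests.
# Everything here is written from first principles, independent of the
# package's own code paths.

# multinomial log-likelihood of a 3x3 genotype count table under random
# union of gametes with haplotype frequencies parameterized by pAB
# (reference-reference) given fixed allele frequencies pA, pB
loglik3x3 <- function(counts, pAB, pA, pB) {
  pAb <- pA - pAB
  paB <- pB - pAB
  pab <- 1 - pA - pB + pAB
  if (min(pAb, paB, pab, pAB) < -1e-12) return(-Inf)
  probs <- matrix(c(
    pAB^2,         2 * pAB * pAb,               pAb^2,
    2 * pAB * paB, 2 * (pAB * pab + pAb * paB), 2 * pAb * pab,
    paB^2,         2 * paB * pab,               pab^2
  ), 3, 3, byrow = TRUE)
  keep <- counts > 0
  if (any(probs[keep] <= 0)) return(-Inf)
  sum(counts[keep] * log(probs[keep]))
}

# brute-force maximizer of the likelihood over the one free haplotype
# frequency (allele frequencies are fixed by the genotype margins)
grid_r2 <- function(counts, step = 1e-4) {
  counts <- matrix(as.numeric(counts), 3, 3)
  n <- sum(counts)
  pA <- sum(counts * (2 - matrix(0:2, 3, 3))) / (2 * n)
  pB <- sum(counts * (2 - matrix(0:2, 3, 3, byrow = TRUE))) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(p) loglik3x3(counts, p, pA, pB), numeric(1))
  best <- grid[which.max(ll)]
  # refine around the coarse maximizer (r2 is sensitive to pAB when the
  # allele frequencies are extreme, so the coarse step alone is too blunt)
  fine <- seq(max(lo, best - 2 * step), min(hi, best + 2 * step),
              by = step / 1000)
  llf <- vapply(fine, function(p) loglik3x3(counts, p, pA, pB), numeric(1))
  best <- fine[which.max(llf)]
  (best - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# two-locus genotype sample of n diploids from Dirichlet(1,1,1,1) haplotype
# frequencies; returns list(a, b) genotype vectors (alt dosage)
random_geno_pair <- function(n = 50) {
  repeat {
    h <- stats::rgamma(4, 1)
    h <- h / sum(h)
    # haplotypes 1..4 = AB, Ab, aB, ab ("a"/"b" = alternate allele)
    hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = h), n, 2)
    alt1 <- (hap == 3) + (hap == 4)  # carries alt at locus 1
    alt2 <- (hap == 2) + (hap == 4)  # carries alt at locus 2
    a <- rowSums(alt1)
    b <- rowSums(alt2)
    if (length(unique(a)) > 1 && length(unique(b)) > 1) {
      return(list(a = as.integer(a), b = as.integer(b)))
    }
  }
}

# expand a 3x3 genotype count table into genotype vectors
counts_to_geno <- function(counts) {
  counts <- matrix(as.integer(counts), 3, 3)
  idx <- which(counts > 0, arr.ind = TRUE)
  a <- rep(idx[, 1] - 1L, counts[idx])
  b <- rep(idx[, 2] - 1L, counts[idx])
  list(a = a, b = b)
}

# quick genotype_matrix on one chromosome with evenly spaced positions
make_gm <- function(calls, chrom = "chr1", spacing = 1000L) {
  calls <- as.matrix(calls)
  genotype_matrix(
    calls,
    loci = data.frame(chrom = chrom, pos = spacing * seq_len(ncol(calls)),
                      id = NA, ref = "A", alt = "G"),
    samples = sprintf("s%03d", seq_len(nrow(calls)))
  )
}

# mean silhouette width of 1-D values under given labels
silhouette_1d <- function(x, labels) {
  labels <- as.character(labels)
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(abs(x[i] - x[labels == l]))
    }, numeric(1)))
    if (is.nan(a)) a <- 0
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# window-index boundary error of a called region against the true span
region_window_error <- function(scan, regions, chrom, true_span) {
  w <- scan$mds[scan$mds$chrom == chrom, ]
  wt1 <- w$window[w$start <= true_span[1] & w$end >= true_span[1]][1]
  wt2 <- w$window[w$start <= true_span[2] & w$end >= true_span[2]][1]
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0 || is.na(wt1) || is.na(wt2)) return(Inf)
  min(pmax(abs(r$first_window - wt1), abs(r$last_window - wt2)))
}

# tiny VCF text fixture written to a temp file
write_mini_vcf <- function(body_lines, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines
  ), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
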