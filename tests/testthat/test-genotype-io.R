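test_that("read_vcf filters on minor allele frequency", {
  path <- write_mini_vcf(c(
    vcf_row("chr1", 100, "A", "G", c("0/0", "0/1", "1/1")),
    vcf_row("chr1", 200, "C", "T", c("0/0", "0/0", "0/0"))
  ))
  gm <- read_vcf(path, min_maf = 0.05, verbose = FALSE)
  expect_equal(n_loci(gm), 1)
  expect_equal(gm$loci$pos, 100L)
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L, 2L))

  gm0 <- read_vcf(path, min_maf = 0, verbose = FALSE)
  expect_equal(n_loci(gm0), 2)
})

test_that("read_vcf skips non-SNP records, ignores phase, masks half-missing", {
  path <- write_mini_vcf(c(
    vcf_row("chr1", 50, "AT", "A", c("0/0", "0/1", "1/1")),     # indel
    vcf_row("chr1", 100, "A", "G,T", c("0/0", "0/1", "1/1")),   # multi-allelic
    vcf_row("chr1", 150, "A", "G", c("0|1", "./1", "./."))
  ))
  expect_message(gm <- read_vcf(path, min_maf = 0), "skipped 2")
  expect_equal(n_loci(gm), 1)
  expect_equal(unname(gm$calls[, 1]), c(1L, NA_integer_, NA_integer_))
})

test_that("read_vcf errors usefully on missing files and empty results", {
  expect_error(read_vcf(tempfile()), "no such file")
  path <- write_mini_vcf(
    vcf_row("chr1", 100, "A", "G", c("0/0", "0/0", "0/0"))
  )
  expect_error(read_vcf(path, min_maf = 0.05, verbose = FALSE),
               "empty matrix")
})

test_that("write_vcf emits GT codes and rejects empty input", {
  gm <- make_gm(matrix(1L, 1, 1))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  body <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  expect_length(body, 1)
  expect_match(body, "\t0/1$")
  gm_empty <- gm
  gm_empty$samples <- character(0)
  gm_empty$calls <- gm$calls[integer(0), , drop = FALSE]
  expect_error(write_vcf(gm_empty, tempfile()), "empty")
})

test_that("simulated data round-trips through VCF exactly", {
  sim <- simulate_dataset(sim_config(seed = 31))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$gm, path)
  back <- read_vcf(path, min_maf = 0, max_missing = 1, verbose = FALSE)
  expect_identical(unname(back$calls), unname(sim$gm$calls))
  expect_identical(back$loci, sim$gm$loci)
  expect_identical(back$samples, sim$gm$samples)
})

test_that("subset_region obeys interval semantics", {
  gm <- make_gm(matrix(0:2, 3, 4), spacing = 100L)  # pos 100..400
  expect_equal(n_loci(subset_region(gm, "chr1", 500, 900)), 0)
  expect_identical(subset_region(gm, "chr1", 1, 400)$loci, gm$loci)
  expect_equal(subset_region(gm, "chr1", 200, 300)$loci$pos, c(200L, 300L))
  expect_error(subset_region(gm, "chrX", 1, 10), "available: chr1")

  sim <- simulate_dataset(sim_config(seed = 5))
  cfg <- sim$truth$config
  reg <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start, cfg$inv_end)
  expect_identical(locus_key(reg$loci), sim$truth$region_loci)
})

test_that("every retained locus satisfies the MAF filter by direct count", {
  sim <- simulate_dataset(sim_config(seed = 8, n_samples = 60,
                                     loci_per_chrom = 80))
  gm <- filter_loci(sim$gm, min_maf = 0.1, verbose = FALSE)
  for (j in seq_len(n_loci(gm))) {
    g <- gm$calls[, j]
    g <- g[!is.na(g)]
    alt <- sum(g) / (2 * length(g))
    expect_gte(min(alt, 1 - alt), 0.1)
  }
})

test_that("position subsetting commutes with MAF filtering", {
  sim <- simulate_dataset(sim_config(seed = 12, n_samples = 50,
                                     loci_per_chrom = 100))
  gm <- sim$gm
  a <- subset_region(filter_loci(gm, min_maf = 0.1, verbose = FALSE),
                     "chr1", 5e6, 2e7)
  b <- filter_loci(subset_region(gm, "chr1", 5e6, 2e7),
                   min_maf = 0.1, verbose = FALSE)
  expect_identical(a$loci, b$loci)
  expect_identical(a$calls, b$calls)
})

test_that("genotype_matrix validation rejects malformed input", {
  expect_error(make_gm(matrix(3L, 2, 2)), "codes")
  expect_error(
    genotype_matrix(matrix(0L, 1, 2),
                    data.frame(chrom = "c1", pos = c(200L, 100L), id = NA,
                               ref = "A", alt = "G")),
    "sorted"
  )
  expect_error(
    genotype_matrix(matrix(0L, 1, 3),
                    data.frame(chrom = c("c1", "c2", "c1"),
                               pos = c(1L, 1L, 2L), id = NA,
                               ref = "A", alt = "G")),
    "contiguous"
  )
})
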