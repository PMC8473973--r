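# three clean karyotype groups: REF all-0, HET all-1, ALT all-2 genotypes
three_group_gm <- function(n_ref = 70, n_het = 25, n_alt = 5, n_loci = 20) {
  make_gm(rbind(
    matrix(0L, n_ref, n_loci),
    matrix(1L, n_het, n_loci),
    matrix(2L, n_alt, n_loci)
  ))
}

test_that("region_pca orients PC1 by alternate-allele dosage", {
  gm <- three_group_gm()
  coords <- region_pca(gm)
  expect_lt(mean(coords$pc1[1:70]), 0)     # reference group negative
  expect_gt(mean(coords$pc1[96:100]), 0)   # alternate group positive
  expect_error(region_pca(make_gm(matrix(1L, 10, 4))), "resolution")
})

test_that("separated clusters with heterozygote excess are assigned 70/25/5", {
  gm <- three_group_gm()
  asg <- assign_karyotypes(region_pca(gm), gm)
  expect_equal(sum(asg$karyotype == "REF_HOM"), 70)
  expect_equal(sum(asg$karyotype == "HET"), 25)
  expect_equal(sum(asg$karyotype == "ALT_HOM"), 5)
  sm <- summarize_karyotypes(asg)
  expect_equal(as.numeric(sm$frequencies), c(0.70, 0.25, 0.05))
  expect_equal(sm$q, 0.175)
})

test_that("a central cluster without heterozygote excess trips the gate", {
  # middle group sits between the flanks on PC1 but carries no hets
  calls <- rbind(
    matrix(0L, 70, 20),
    cbind(matrix(2L, 25, 10), matrix(0L, 25, 10)),
    matrix(2L, 5, 20)
  )
  gm <- make_gm(calls)
  expect_message(asg <- assign_karyotypes(region_pca(gm), gm),
                 "UNASSIGNED")
  expect_true(all(asg$karyotype == "UNASSIGNED"))
  expect_error(summarize_karyotypes(asg), "no assigned samples")
})

test_that("karyotype labels are invariant to PC1 sign and sample order", {
  gm <- three_group_gm()
  coords <- region_pca(gm)
  asg <- assign_karyotypes(coords, gm)
  flipped <- coords
  flipped$pc1 <- -coords$pc1
  asg_f <- assign_karyotypes(flipped, gm)
  expect_equal(asg_f$karyotype, asg$karyotype)

  perm <- sample(seq_len(n_samples(gm)))
  gm_p <- invscan:::subset_samples(gm, perm)
  asg_p <- assign_karyotypes(region_pca(gm_p), gm_p)
  expect_equal(asg_p$karyotype[order(perm)], asg$karyotype)
})

test_that("individual heterozygosity uses the region-level denominator", {
  calls <- rbind(
    rep(1L, 8),               # het at every locus
    rep(0L, 8),               # no hets
    c(rep(1L, 4), rep(0L, 4)) # half
  )
  gm <- make_gm(calls)
  h <- individual_heterozygosity(gm)
  expect_equal(unname(h), c(1, 0, 0.5))
  # loci with no het anywhere drop out of the denominator
  calls2 <- cbind(calls, matrix(c(0L, 0L, 2L), 3, 2))
  h2 <- individual_heterozygosity(make_gm(calls2))
  expect_equal(unname(h2), c(1, 0, 0.5))
  # per-sample denominator counts that sample's non-missing loci instead
  h3 <- individual_heterozygosity(make_gm(calls2),
                                  per_sample_denominator = TRUE)
  expect_equal(unname(h3), c(0.8, 0, 0.4))
})

test_that("all-REF assignments give q = 0", {
  asg <- data.frame(sample = letters[1:5], pc1 = 0, pc2 = 0,
                    karyotype = "REF_HOM", het_rate = 0)
  sm <- summarize_karyotypes(asg)
  expect_equal(sm$q, 0)
  expect_equal(as.numeric(sm$frequencies), c(1, 0, 0))
})

test_that("region PCA separates karyotypes while genome-wide PCA does not", {
  sim <- simulate_dataset(sim_config(seed = 17))
  cfg <- sim$truth$config
  region_gm <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start,
                             cfg$inv_end)
  reg_sil <- silhouette_1d(region_pca(region_gm)$pc1, sim$truth$karyotype)
  expect_gt(reg_sil, 0.8)
  genome_sil <- silhouette_1d(region_pca(sim$gm)$pc1, sim$truth$karyotype)
  # genome-wide clustering by karyotype is strictly weaker than at the
  # region; the simulated background carries no competing population
  # structure, so the inversion still bleeds into genome-wide PC1 and the
  # contrast is relative rather than absolute
  expect_lt(genome_sil, reg_sil - 0.1)
})

test_that("karyotype recovery matches simulator truth at defaults", {
  sim <- simulate_dataset(sim_config(seed = 23))
  cfg <- sim$truth$config
  region_gm <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start,
                             cfg$inv_end)
  asg <- assign_karyotypes(region_pca(region_gm), region_gm)
  expect_gte(mean(asg$karyotype == sim$truth$karyotype), 0.95)
  sm <- summarize_karyotypes(asg)
  # recovered arrangement frequency within the binomial 95% CI of q = 0.17
  ci <- 1.96 * sqrt(0.17 * 0.83 / (2 * 142))
  expect_lt(abs(sm$q - 0.17), ci + 1e-12)
})

test_that("a sample without the rare homokaryote still genotypes correctly", {
  # drop every ALT_HOM carrier: a two-cluster REF/HET geometry remains
  sim <- simulate_dataset(sim_config(seed = 37))
  keep <- which(sim$truth$karyotype != "ALT_HOM")
  cfg <- sim$truth$config
  region_gm <- invscan:::subset_samples(
    subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start, cfg$inv_end), keep
  )
  expect_message(
    asg <- assign_karyotypes(region_pca(region_gm), region_gm),
    "rare homokaryote"
  )
  expect_gte(mean(asg$karyotype == sim$truth$karyotype[keep]), 0.95)
  expect_false(any(asg$karyotype == "ALT_HOM"))
})

test_that("zero-divergence data never yields three karyotype clusters", {
  sim <- simulate_dataset(sim_config(seed = 29, delta = 0))
  cfg <- sim$truth$config
  region_gm <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start,
                             cfg$inv_end)
  suppressMessages(asg <- assign_karyotypes(region_pca(region_gm), region_gm))
  expect_true(all(asg$karyotype == "UNASSIGNED"))
})
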