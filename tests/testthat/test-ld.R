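test_that("perfect coupling gives r2 = 1 and equilibrium gives r2 = 0", {
  a <- c(0L, 0L, 1L, 1L, 2L, 2L)
  r <- r2_em(a, a)
  expect_true(r$defined)
  expect_equal(r$r2, 1, tolerance = 1e-8)

  # counts exactly proportional to independent loci at p = q = 0.5
  tab <- outer(c(1, 2, 1), c(1, 2, 1))
  g <- counts_to_geno(tab)
  r0 <- r2_em(g$a, g$b)
  expect_equal(r0$r2, 0, tolerance = 1e-10)
  expect_equal(r0$D, 0, tolerance = 1e-10)
  expect_equal(sum(r0$hap_freqs), 1, tolerance = 1e-12)
})

test_that("EM matches the brute-force likelihood-grid oracle", {
  set.seed(101)
  for (i in 1:25) {
    g <- random_geno_pair(50)
    em <- r2_em(g$a, g$b)
    gr <- grid_r2(table(factor(g$a, 0:2), factor(g$b, 0:2)))
    expect_lt(abs(em$r2 - gr), 1e-4)
  }
})

test_that("EM log-likelihood at the solution is the global maximum", {
  set.seed(103)
  for (i in 1:10) {
    g <- random_geno_pair(40)
    counts <- table(factor(g$a, 0:2), factor(g$b, 0:2))
    em <- r2_em(g$a, g$b)
    n <- sum(counts)
    pA <- em$hap_freqs[["pAB"]] + em$hap_freqs[["pAb"]]
    pB <- em$hap_freqs[["pAB"]] + em$hap_freqs[["paB"]]
    ll_em <- loglik3x3(matrix(as.numeric(counts), 3, 3),
                       em$hap_freqs[["pAB"]], pA, pB)
    ll_init <- loglik3x3(matrix(as.numeric(counts), 3, 3), pA * pB, pA, pB)
    expect_gte(ll_em, ll_init - 1e-9)
    grid <- seq(max(0, pA + pB - 1), min(pA, pB), by = 1e-4)
    ll_grid <- max(vapply(grid, function(p) {
      loglik3x3(matrix(as.numeric(counts), 3, 3), p, pA, pB)
    }, numeric(1)))
    expect_gte(ll_em, ll_grid - 1e-6)
  }
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(107)
  g <- random_geno_pair(30)
  r <- r2_em(g$a, g$b)
  expect_equal(r2_em(g$b, g$a)$r2, r$r2, tolerance = 1e-10)
  expect_equal(r2_em(2L - g$a, g$b)$r2, r$r2, tolerance = 1e-10)
  expect_equal(r2_em(g$a, 2L - g$b)$r2, r$r2, tolerance = 1e-10)
})

test_that("monomorphic and missing-heavy pairs are flagged undefined", {
  r <- r2_em(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L))
  expect_false(r$defined)
  expect_true(is.na(r$r2))
  expect_error(r2_em(c(0L, NA, NA), c(NA, 1L, 2L)), "non-missing")
})

test_that("vectorized pairwise LD agrees with the per-pair EM", {
  sim <- simulate_dataset(sim_config(seed = 41, n_samples = 60,
                                     loci_per_chrom = 40))
  tab <- pairwise_ld(sim$gm, loci_idx = which(sim$gm$loci$chrom == "chr2"))
  set.seed(1)
  for (k in sample(nrow(tab), 40)) {
    r <- r2_em(sim$gm$calls[, tab$idx_a[k]], sim$gm$calls[, tab$idx_b[k]])
    if (r$defined) {
      # both paths stop within the EM tolerance of the optimum, possibly
      # approaching from different restart directions
      expect_lt(abs(tab$r2[k] - r$r2), 1e-6)
      expect_equal(tab$n_used[k], r$n_used)
    } else {
      expect_true(is.na(tab$r2[k]))
    }
  }
})

test_that("chromosome_ld enumerates pairs and reports low null LD", {
  gm <- make_gm(matrix(c(0L, 1L, 2L, 0L, 0L, 1L, 2L, 2L), 4, 2))
  tab <- chromosome_ld(gm, "chr1", verbose = FALSE)
  expect_equal(nrow(tab), 1)
  expect_error(chromosome_ld(gm, "chrZ", verbose = FALSE), "available")

  # a chromosome simulated in linkage equilibrium averages r2 ~ 1/n
  sim <- simulate_dataset(sim_config(seed = 43))
  tab1 <- chromosome_ld(sim$gm, "chr1", verbose = FALSE)
  expect_lt(attr(tab1, "mean_r2"), 0.02)
})

test_that("stratified LD contrasts pooled against within-karyotype means", {
  sim <- simulate_dataset(sim_config(seed = 47))
  cfg <- sim$truth$config
  region_gm <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start,
                             cfg$inv_end)
  asg <- assign_karyotypes(region_pca(region_gm), region_gm)
  strat <- suppressWarnings(stratified_ld(region_gm, asg))
  pooled <- strat$mean_r2[strat$group == "POOLED"]
  within_ref <- strat$mean_r2[strat$group == "REF_HOM"]
  expect_gt(pooled, 3 * within_ref)

  # single-sample groups are skipped with a warning
  asg2 <- asg
  asg2$karyotype[asg2$karyotype == "ALT_HOM"] <-
    c("ALT_HOM", rep("UNASSIGNED", sum(asg2$karyotype == "ALT_HOM") - 1))
  expect_warning(s2 <- stratified_ld(region_gm, asg2), "skipped")
  expect_true(is.na(s2$mean_r2[s2$group == "ALT_HOM"]))
})

test_that("zero-divergence data shows no stratification effect", {
  sim <- simulate_dataset(sim_config(seed = 53, delta = 0, q = 0.5))
  cfg <- sim$truth$config
  region_gm <- subset_region(sim$gm, cfg$inv_chrom, cfg$inv_start,
                             cfg$inv_end)
  asg <- data.frame(sample = sim$gm$samples, pc1 = 0, pc2 = 0,
                    karyotype = sim$truth$karyotype,
                    het_rate = 0)
  strat <- suppressWarnings(stratified_ld(region_gm, asg))
  pooled <- strat$mean_r2[strat$group == "POOLED"]
  within <- strat$mean_r2[strat$group != "POOLED"]
  within <- within[!is.na(within)]
  expect_true(all(pooled < 1.5 * pmax(within, 1e-3) + 0.01))
})

test_that("LD networks apply edge and iterative degree filters", {
  # clique of 6 loci at r2 = 0.9 plus weak isolated pairs
  pos <- 1:10 * 1000L
  mk_tab <- function(i, j, r2) {
    data.frame(chrom_a = "c1", pos_a = pos[i], chrom_b = "c1",
               pos_b = pos[j], idx_a = i, idx_b = j, n_used = 50,
               D = 0.1, r2 = r2, converged = TRUE)
  }
  cl <- t(combn(1:6, 2))
  tab <- rbind(
    do.call(rbind, lapply(seq_len(nrow(cl)), function(k) {
      mk_tab(cl[k, 1], cl[k, 2], 0.9)
    })),
    mk_tab(7, 8, 0.95),   # isolated strong pair -> pruned by degree
    mk_tab(9, 10, 0.1)    # below edge threshold
  )
  net <- ld_network(tab)
  expect_equal(nrow(net$nodes), 6)
  expect_equal(length(unique(net$nodes$component)), 1)
  expect_true(all(net$nodes$degree >= 4))

  # idempotence: re-filtering the retained network changes nothing
  keep <- tab$r2 >= 0.4 &
    paste(tab$pos_a) %in% net$nodes$pos & paste(tab$pos_b) %in% net$nodes$pos
  net2 <- ld_network(tab[keep, ])
  expect_setequal(net2$nodes$name, net$nodes$name)

  expect_equal(nrow(ld_network(mk_tab(1, 2, 0.2))$nodes), 0)
})

test_that("the simulated inversion forms one spanning network component", {
  sim <- simulate_dataset(sim_config(seed = 59, delta = 0.95))
  cfg <- sim$truth$config
  tab <- pairwise_ld(sim$gm,
                     loci_idx = which(sim$gm$loci$chrom == cfg$inv_chrom))
  net <- ld_network(tab)
  expect_equal(length(unique(net$nodes$component)), 1)
  truth_keys <- sim$truth$region_loci
  node_keys <- net$nodes$name
  jacc <- length(intersect(truth_keys, node_keys)) /
    length(union(truth_keys, node_keys))
  expect_gte(jacc, 0.8)
})
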