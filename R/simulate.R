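#' Configuration for the planted-inversion simulator
#'
#' Defaults describe the study condition the package is validated against:
#' 142 diploid samples, three 25-Mb chromosomes of ~494 SNPs each, and one
#' chromosome carrying a low-frequency inversion polymorphism spanning
#' 12.54-13.7 Mb represented by 26 SNPs. Two arrangements (ancestral /
#' inverted) segregate at inverted-arrangement frequency `q`; a fraction
#' `d` of region loci is arrangement-differentiated with allele-frequency
#' difference `delta`; `theta_anc` and `theta_inv` set the within-
#' arrangement minor-allele-frequency scales (the derived arrangement is
#' younger, hence less diverse: `theta_inv <= theta_anc`).
#'
#' @param n_samples Number of diploid samples (default 142).
#' @param n_chromosomes Number of chromosomes (default 3).
#' @param loci_per_chrom SNPs per chromosome (default 494).
#' @param chrom_length_bp Chromosome length in bp (default 25e6).
#' @param inv_chrom Chromosome carrying the inversion (default `"chr2"`).
#' @param inv_start,inv_end Inversion span in bp (defaults 12,540,000 and
#'   13,700,000).
#' @param n_region_loci SNPs inside the inversion (default 26).
#' @param q Inverted-arrangement frequency (default 0.17).
#' @param d Fraction of region loci that are arrangement-differentiated
#'   (default 0.9).
#' @param delta Allele-frequency difference between arrangements at
#'   differentiated loci (default 0.8).
#' @param theta_anc,theta_inv Within-arrangement minor-allele-frequency
#'   scales (defaults 0.15 and 0.05).
#' @param missing_rate Per-call missing probability (default 0.02).
#' @param seed Integer RNG seed (optional).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 142, n_chromosomes = 3,
                       loci_per_chrom = 494, chrom_length_bp = 25e6,
                       inv_chrom = "chr2", inv_start = 12540000L,
                       inv_end = 13700000L, n_region_loci = 26,
                       q = 0.17, d = 0.9, delta = 0.8,
                       theta_anc = 0.15, theta_inv = 0.05,
                       missing_rate = 0.02, seed = NULL) {
  cfg <- list(
    n_samples = n_samples, n_chromosomes = n_chromosomes,
    loci_per_chrom = loci_per_chrom, chrom_length_bp = chrom_length_bp,
    inv_chrom = inv_chrom, inv_start = as.integer(inv_start),
    inv_end = as.integer(inv_end), n_region_loci = n_region_loci,
    q = q, d = d, delta = delta, theta_anc = theta_anc,
    theta_inv = theta_inv, missing_rate = missing_rate, seed = seed
  )
  stopifnot(
    q >= 0, q <= 1, d >= 0, d <= 1, delta >= 0, delta <= 1,
    missing_rate >= 0, missing_rate <= 1,
    theta_inv <= theta_anc,
    inv_start >= 1, inv_end <= chrom_length_bp, inv_start < inv_end,
    inv_chrom %in% paste0("chr", seq_len(n_chromosomes)),
    n_region_loci <= loci_per_chrom
  )
  class(cfg) <- "sim_config"
  cfg
}

# arrangement-specific allele frequencies for the region loci
# returns data.frame(p_anc, p_inv, differentiated)
region_freqs <- function(cfg) {
  L <- cfg$n_region_loci
  differentiated <- stats::runif(L) < cfg$d
  p_anc <- p_inv <- numeric(L)
  n_clipped <- 0L
  for (l in seq_len(L)) {
    if (differentiated[l]) {
      # inverted-arrangement minor frequency on its own scale; the
      # ancestral minor frequency then follows from the exact-delta
      # constraint m_anc + m_inv = 1 - delta
      m_inv <- stats::runif(1, 0.005, max(0.01, 2 * cfg$theta_inv - 0.005))
      m_anc <- (1 - cfg$delta) - m_inv
      if (m_anc < 0.005 || m_anc > 0.5) {
        m_anc <- min(max(m_anc, 0.005), 0.5)
        n_clipped <- n_clipped + 1L
      }
      # reference-aligned coding: the reference allele is the allele common
      # in the ancestral arrangement, so the alternate allele is rare in
      # the ancestral background and common in the inverted one
      p_anc[l] <- m_anc
      p_inv[l] <- min(p_anc[l] + cfg$delta, 0.995)
    } else {
      p_anc[l] <- p_inv[l] <- stats::runif(1, 0.005,
                                           max(0.01, 2 * cfg$theta_anc))
    }
  }
  if (n_clipped > 0) {
    message("region_freqs: clipped ", n_clipped,
            " infeasible frequency combination(s) to [0.005, 0.5]")
  }
  data.frame(p_anc = p_anc, p_inv = p_inv, differentiated = differentiated)
}

#' Simulate a genotype dataset with a planted inversion
#'
#' Background loci are in Hardy-Weinberg and linkage equilibrium (allele
#' frequency uniform on `[0.05, 0.5]`, genotypes `Binomial(2, p)` per
#' sample). Each sample draws an inverted-arrangement count
#' `a ~ Binomial(2, q)`; at region loci its two haplotypes draw alleles
#' independently from their own arrangement's frequency — free
#' recombination within an arrangement, none between — which yields the
#' inversion signature the pipeline detects: elevated pooled LD, low
#' within-karyotype LD, three PCA clusters, heterokaryotype heterozygosity
#' excess. Calls are masked missing at `missing_rate`. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `gm` (a [genotype_matrix()]) and `truth` (list with
#'   `karyotype` per-sample labels, `arrangement_count`, `region_freqs`,
#'   `region_loci` (keys `chrom:pos`), `region_idx` (locus columns in
#'   `gm`), and the `config`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("sample_%03d", seq_len(n))
  a <- stats::rbinom(n, 2, cfg$q)  # inverted-arrangement count per sample
  h1_inv <- a == 2 | a == 1        # arrangement of each haplotype
  h2_inv <- a == 2
  calls_list <- list()
  loci_list <- list()
  region_idx <- integer(0)
  rf <- NULL
  offset <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", ci)
    is_inv <- ch == cfg$inv_chrom
    n_bg <- cfg$loci_per_chrom - if (is_inv) cfg$n_region_loci else 0L
    # background positions uniform over the chromosome, excluding the
    # inversion interval on its chromosome (uniform draw on the reduced
    # coordinate space, then shift past the interval)
    if (is_inv) {
      len_region <- cfg$inv_end - cfg$inv_start + 1L
      pos_bg <- sort(sample.int(cfg$chrom_length_bp - len_region, n_bg))
      shift <- pos_bg >= cfg$inv_start
      pos_bg[shift] <- pos_bg[shift] + len_region
    } else {
      pos_bg <- sort(sample.int(cfg$chrom_length_bp, n_bg))
    }
    p_bg <- stats::runif(n_bg, 0.05, 0.5)
    g_bg <- matrix(stats::rbinom(n * n_bg, 2, rep(p_bg, each = n)), n, n_bg)
    if (is_inv) {
      rf <- region_freqs(cfg)
      pos_r <- sort(sample(seq(cfg$inv_start, cfg$inv_end),
                           cfg$n_region_loci))
      g_r <- matrix(0L, n, cfg$n_region_loci)
      for (l in seq_len(cfg$n_region_loci)) {
        p1 <- ifelse(h1_inv, rf$p_inv[l], rf$p_anc[l])
        p2 <- ifelse(h2_inv, rf$p_inv[l], rf$p_anc[l])
        g_r[, l] <- stats::rbinom(n, 1, p1) + stats::rbinom(n, 1, p2)
      }
      pos <- c(pos_bg, pos_r)
      ord <- order(pos)
      calls <- cbind(g_bg, g_r)[, ord, drop = FALSE]
      from_region <- c(rep(FALSE, n_bg), rep(TRUE, cfg$n_region_loci))[ord]
      region_idx <- offset + which(from_region)
      pos <- pos[ord]
    } else {
      calls <- g_bg
      pos <- pos_bg
    }
    calls_list[[ci]] <- calls
    loci_list[[ci]] <- data.frame(
      chrom = ch, pos = pos, id = NA_character_, ref = "A", alt = "G",
      stringsAsFactors = FALSE
    )
    offset <- offset + length(pos)
  }
  calls <- do.call(cbind, calls_list)
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }
  loci <- do.call(rbind, loci_list)
  gm <- genotype_matrix(calls, loci, samples = samples)
  karyotype <- c("REF_HOM", "HET", "ALT_HOM")[a + 1L]
  rf$chrom <- cfg$inv_chrom
  rf$pos <- gm$loci$pos[region_idx]
  list(
    gm = gm,
    truth = list(
      karyotype = stats::setNames(karyotype, samples),
      arrangement_count = stats::setNames(a, samples),
      region_freqs = rf,
      region_loci = locus_key(gm$loci[region_idx, ]),
      region_idx = region_idx,
      config = cfg
    )
  )
}

#' Write a simulated dataset to disk as a reusable fixture
#'
#' Emits `sim.vcf` (GT-only VCF 4.2), `truth.tsv` (sample, karyotype,
#' arrangement count), `region_loci.tsv` and `config.yaml`. Output is
#' byte-identical for identical configurations (including seed).
#'
#' @param cfg A [sim_config()]; must carry a `seed` for reproducible files.
#' @param outdir Writable output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_fixture <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(cfg)
  files <- c(
    vcf = file.path(outdir, "sim.vcf"),
    truth = file.path(outdir, "truth.tsv"),
    region = file.path(outdir, "region_loci.tsv"),
    config = file.path(outdir, "config.yaml")
  )
  write_vcf(sim$gm, files[["vcf"]])
  utils::write.table(
    data.frame(sample = names(sim$truth$karyotype),
               karyotype = sim$truth$karyotype,
               arrangement_count = sim$truth$arrangement_count),
    files[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(sim$truth$region_freqs[, c("chrom", "pos", "p_anc",
                                                "p_inv", "differentiated")],
                     files[["region"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(cfg), files[["config"]])
  invisible(files)
}
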