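#' EM estimate of gametic r-squared for one locus pair
#'
#' Maximum-likelihood haplotype frequencies for two unphased biallelic loci
#' are obtained by expectation-maximization over the 3x3 genotype table:
#' every cell except the double heterozygote has known haplotype
#' composition; the double-heterozygote mass is split between the coupling
#' (AB/ab) and repulsion (Ab/aB) phases in proportion to the current
#' frequency estimates. Because the two-locus likelihood can be multimodal
#' in the haplotype frequency, the EM is run from linkage equilibrium and
#' from both ends of the feasible frequency interval, keeping the
#' highest-likelihood solution.
#' `D = pAB - pA pB` and `r2 = D^2 / (pA pa pB pb)` are derived from the
#' converged frequencies. Allele "A"/"B" denotes the reference allele at
#' each locus.
#'
#' @param geno_a,geno_b Genotype vectors (codes 0/1/2/NA) for the two loci
#'   over the same samples.
#' @param tol Convergence tolerance on the largest haplotype-frequency
#'   change (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List of class `ld_result`: `hap_freqs` (named `pAB`, `pAb`,
#'   `paB`, `pab`), `D`, `r2`, `n_used`, `converged`, `defined` (`FALSE`
#'   when a locus is monomorphic among the jointly non-missing samples, in
#'   which case `r2` is `NA`).
#' @export
r2_em <- function(geno_a, geno_b, tol = 1e-8, max_iter = 1000) {
  ok <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[ok]
  b <- geno_b[ok]
  n <- length(a)
  if (n < 2) stop("need at least 2 samples with both genotypes non-missing")
  counts <- table(factor(a, levels = 0:2), factor(b, levels = 0:2))
  em_from_counts(counts, tol = tol, max_iter = max_iter)
}

# EM on a 3x3 genotype count table (rows: dosage at locus A, cols: locus B)
em_from_counts <- function(counts, tol = 1e-8, max_iter = 1000) {
  counts <- matrix(as.numeric(counts), 3, 3)
  n <- sum(counts)
  # reference-allele frequencies from the margins (invariant under EM)
  pA <- sum(counts * (2 - matrix(0:2, 3, 3))) / (2 * n)
  pB <- sum(counts * (2 - matrix(0:2, 3, 3, byrow = TRUE))) / (2 * n)
  res <- list(
    hap_freqs = c(pAB = pA * pB, pAb = pA * (1 - pB),
                  paB = (1 - pA) * pB, pab = (1 - pA) * (1 - pB)),
    D = 0, r2 = NA_real_, n_used = n, converged = TRUE, defined = FALSE
  )
  class(res) <- "ld_result"
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(res)
  # the two-locus likelihood can be multimodal in pAB: restart the EM from
  # linkage equilibrium and from both ends of the feasible interval, and
  # keep the highest-likelihood solution
  run_em <- function(pAB0) {
    pAB <- pAB0
    pAb <- pA - pAB
    paB <- pB - pAB
    pab <- 1 - pA - pB + pAB
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      denom <- pAB * pab + pAb * paB
      w <- if (denom > 0) pAB * pab / denom else 0.5
      eAB <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + w * counts[2, 2]
      eAb <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3] + (1 - w) * counts[2, 2]
      eaB <- 2 * counts[3, 1] + counts[2, 1] + counts[3, 2] + (1 - w) * counts[2, 2]
      eab <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + w * counts[2, 2]
      pn <- c(eAB, eAb, eaB, eab) / (2 * n)
      delta <- max(abs(pn - c(pAB, pAb, paB, pab)))
      pAB <- pn[1]; pAb <- pn[2]; paB <- pn[3]; pab <- pn[4]
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    hap <- c(pAB = pAB, pAb = pAb, paB = paB, pab = pab)
    list(hap = hap, converged = converged,
         loglik = genotype_loglik(counts, hap))
  }
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  eps <- 1e-6 + 1e-4 * (hi - lo)
  fits <- lapply(c(pA * pB, lo + eps, hi - eps), run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  D <- best$hap[["pAB"]] - pA * pB
  res$hap_freqs <- best$hap
  res$D <- D
  res$r2 <- min(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 1)
  res$converged <- best$converged
  res$defined <- TRUE
  res
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype freqs
# (random union of gametes); used by EM diagnostics and test oracles
genotype_loglik <- function(counts, hap) {
  pAB <- hap[[1]]; pAb <- hap[[2]]; paB <- hap[[3]]; pab <- hap[[4]]
  probs <- matrix(c(
    pAB^2,       2 * pAB * pAb,             pAb^2,
    2 * pAB * paB, 2 * (pAB * pab + pAb * paB), 2 * pAb * pab,
    paB^2,       2 * paB * pab,             pab^2
  ), 3, 3, byrow = TRUE)
  sum(counts[counts > 0] * log(probs[counts > 0]))
}

# Vectorized EM r2 over all unordered pairs of the given locus columns.
# Pair counts come from indicator-matrix cross-products; the EM itself runs
# on flat vectors over the upper triangle, shrinking to the still-active
# (unconverged) pairs each iteration.
# Returns a list of vectors over upper-triangle pairs plus the index map.
ld_em_pairs <- function(calls, tol = 1e-8, max_iter = 1000) {
  m <- !is.na(calls)
  g <- calls
  g[!m] <- 0L
  ind <- lapply(0:2, function(k) {
    z <- (calls == k) & m
    storage.mode(z) <- "double"
    z
  })
  mm <- m
  storage.mode(mm) <- "double"
  ut <- which(upper.tri(diag(ncol(calls))), arr.ind = TRUE)
  up <- function(x) x[ut]
  # genotype-pair counts for every pair: N[x, y] via crossprod of indicators
  N <- lapply(1:3, function(x) lapply(1:3, function(y) {
    up(crossprod(ind[[x]], ind[[y]]))
  }))
  n_used <- up(crossprod(mm, mm))
  altA <- up(crossprod(g, mm))  # alt-dosage sums over pair-complete samples
  altB <- up(crossprod(mm, g))
  pA <- 1 - altA / (2 * n_used)  # reference-allele frequencies
  pB <- 1 - altB / (2 * n_used)
  defined <- n_used >= 2 & pA > 0 & pA < 1 & pB > 0 & pB < 1 &
    !is.na(pA) & !is.na(pB)
  known_AB <- 2 * N[[1]][[1]] + N[[1]][[2]] + N[[2]][[1]]
  known_Ab <- 2 * N[[1]][[3]] + N[[1]][[2]] + N[[2]][[3]]
  known_aB <- 2 * N[[3]][[1]] + N[[2]][[1]] + N[[3]][[2]]
  known_ab <- 2 * N[[3]][[3]] + N[[3]][[2]] + N[[2]][[3]]
  dh <- N[[2]][[2]]
  P <- length(n_used)
  run_em <- function(pAB0) {
    pAB <- pAB0
    pAb <- pA - pAB
    paB <- pB - pAB
    pab <- 1 - pA - pB + pAB
    converged <- rep(FALSE, P)
    act <- which(defined)
    for (it in seq_len(max_iter)) {
      if (length(act) == 0) break
      denom <- pAB[act] * pab[act] + pAb[act] * paB[act]
      w <- pAB[act] * pab[act] / denom
      w[!is.finite(w) | denom <= 0] <- 0.5
      tn <- 2 * n_used[act]
      nAB <- (known_AB[act] + w * dh[act]) / tn
      nAb <- (known_Ab[act] + (1 - w) * dh[act]) / tn
      naB <- (known_aB[act] + (1 - w) * dh[act]) / tn
      nab <- (known_ab[act] + w * dh[act]) / tn
      delta <- pmax(pmax(abs(nAB - pAB[act]), abs(nAb - pAb[act])),
                    pmax(abs(naB - paB[act]), abs(nab - pab[act])))
      pAB[act] <- nAB; pAb[act] <- nAb; paB[act] <- naB; pab[act] <- nab
      done <- delta < tol
      converged[act[done]] <- TRUE
      act <- act[!done]
    }
    ll <- numeric(P)
    probs <- list(
      pAB^2, 2 * pAB * pAb, pAb^2,
      2 * pAB * paB, 2 * (pAB * pab + pAb * paB), 2 * pAb * pab,
      paB^2, 2 * paB * pab, pab^2
    )
    k <- 0
    for (x in 1:3) {
      for (y in 1:3) {
        k <- k + 1
        nxy <- N[[x]][[y]]
        pos <- nxy > 0
        ll[pos] <- ll[pos] + nxy[pos] * log(pmax(probs[[k]][pos], 1e-300))
      }
    }
    list(pAB = pAB, converged = converged, loglik = ll)
  }
  # multimodal likelihood: three starts, keep the best per pair
  lo <- pmax(0, pA + pB - 1)
  hi <- pmin(pA, pB)
  eps <- 1e-6 + 1e-4 * (hi - lo)
  fits <- list(run_em(pA * pB), run_em(lo + eps), run_em(hi - eps))
  ll_mat <- cbind(fits[[1]]$loglik, fits[[2]]$loglik, fits[[3]]$loglik)
  pick <- max.col(ll_mat, ties.method = "first")
  pAB <- cbind(fits[[1]]$pAB, fits[[2]]$pAB, fits[[3]]$pAB)[
    cbind(seq_len(P), pick)]
  converged <- cbind(fits[[1]]$converged, fits[[2]]$converged,
                     fits[[3]]$converged)[cbind(seq_len(P), pick)]
  D <- pAB - pA * pB
  r2 <- pmin(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 1)
  r2[!defined] <- NA_real_
  D[!defined] <- NA_real_
  list(i = ut[, 1], j = ut[, 2], r2 = r2, D = D, n_used = n_used,
       converged = converged, defined = defined)
}

#' All pairwise LD within a set of loci
#'
#' EM-based gametic r-squared for every pair of the selected loci, computed
#' for the selected samples. The EM is vectorized across all pairs
#' simultaneously (the 3x3 genotype-pair counts for every pair are obtained
#' by indicator-matrix cross-products).
#'
#' @param gm A [genotype_matrix()].
#' @param loci_idx Locus column indices (default: all).
#' @param samples Sample identifiers or indices (default: all).
#' @param tol,max_iter EM controls, as in [r2_em()].
#' @return Data frame: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`, `idx_a`,
#'   `idx_b`, `n_used`, `D`, `r2`, `converged`. Pairs with undefined r2
#'   (a locus monomorphic among jointly non-missing samples) have `r2 = NA`.
#' @export
pairwise_ld <- function(gm, loci_idx = seq_len(n_loci(gm)),
                        samples = gm$samples, tol = 1e-8, max_iter = 1000) {
  sub <- subset_samples(subset_loci(gm, loci_idx), samples)
  res <- ld_em_pairs(sub$calls, tol = tol, max_iter = max_iter)
  data.frame(
    chrom_a = sub$loci$chrom[res$i], pos_a = sub$loci$pos[res$i],
    chrom_b = sub$loci$chrom[res$j], pos_b = sub$loci$pos[res$j],
    idx_a = loci_idx[res$i], idx_b = loci_idx[res$j],
    n_used = res$n_used, D = res$D, r2 = res$r2,
    converged = res$converged,
    stringsAsFactors = FALSE
  )
}

#' Chromosome-wide LD table
#'
#' All within-chromosome locus pairs; pairs with undefined r-squared are
#' reported with `NA` and counted in the log.
#'
#' @param gm A [genotype_matrix()].
#' @param chrom Chromosome identifier.
#' @param min_r2_report Only pairs with `r2 >=` this value are returned
#'   (default 0, everything).
#' @param verbose Log undefined-pair count and the mean r2.
#' @return Data frame as in [pairwise_ld()], with attribute `mean_r2` (mean
#'   over defined pairs).
#' @export
chromosome_ld <- function(gm, chrom, min_r2_report = 0, verbose = TRUE) {
  if (!chrom %in% gm$loci$chrom) {
    stop("unknown chromosome '", chrom, "'; available: ",
         paste(unique(gm$loci$chrom), collapse = ", "))
  }
  tab <- pairwise_ld(gm, loci_idx = which(gm$loci$chrom == chrom))
  mean_r2 <- mean(tab$r2, na.rm = TRUE)
  n_undef <- sum(is.na(tab$r2))
  if (verbose) {
    message("chromosome_ld(", chrom, "): ", nrow(tab), " pairs, ",
            n_undef, " undefined, mean r2 = ", signif(mean_r2, 4))
  }
  out <- tab[!is.na(tab$r2) & tab$r2 >= min_r2_report, ]
  attr(out, "mean_r2") <- mean_r2
  attr(out, "n_undefined") <- n_undef
  out
}

#' Region LD stratified by karyotype
#'
#' Mean pairwise r-squared over the region's loci computed over all samples
#' (pooled) and separately within each homokaryote group. A true inversion
#' elevates pooled LD (the arrangements are diverged) but not LD within a
#' homokaryote group, where recombination is free. Homokaryote groups with
#' fewer than `min_group` samples are skipped with a warning. Pairs with
#' undefined r-squared (common within homokaryote groups, where many region
#' alleles are fixed) are excluded from the means and counted.
#'
#' @param region_gm The region [genotype_matrix()].
#' @param assignments A `karyotype_assignment` data frame (same samples).
#' @param min_group Minimum samples per homokaryote group (default 5).
#' @return Data frame: `group` (`POOLED`, `REF_HOM`, `ALT_HOM`),
#'   `n_samples`, `n_pairs_defined`, `n_pairs_undefined`, `mean_r2` (`NA`
#'   for skipped groups).
#' @export
stratified_ld <- function(region_gm, assignments, min_group = 5) {
  groups <- list(POOLED = region_gm$samples)
  for (g in c("REF_HOM", "ALT_HOM")) {
    s <- assignments$sample[assignments$karyotype == g]
    if (length(s) < min_group) {
      warning("stratified_ld: group ", g, " has ", length(s),
              " sample(s) (< ", min_group, "); skipped")
      groups[[g]] <- NULL
    } else {
      groups[[g]] <- s
    }
  }
  rows <- lapply(names(groups), function(nm) {
    tab <- pairwise_ld(region_gm, samples = groups[[nm]])
    data.frame(
      group = nm, n_samples = length(groups[[nm]]),
      n_pairs_defined = sum(!is.na(tab$r2)),
      n_pairs_undefined = sum(is.na(tab$r2)),
      mean_r2 = mean(tab$r2, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  for (g in c("REF_HOM", "ALT_HOM")) {
    if (!g %in% out$group) {
      out <- rbind(out, data.frame(group = g, n_samples = NA_integer_,
                                   n_pairs_defined = NA_integer_,
                                   n_pairs_undefined = NA_integer_,
                                   mean_r2 = NA_real_))
    }
  }
  rownames(out) <- NULL
  out
}
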