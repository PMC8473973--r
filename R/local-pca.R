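#' Partition the genome into non-overlapping SNP windows
#'
#' Each window contains exactly `window_size` consecutive SNPs on one
#' chromosome; the trailing remainder on each chromosome (fewer than
#' `window_size` SNPs) is dropped. Windows never span chromosomes.
#'
#' @param gm A [genotype_matrix()].
#' @param window_size Number of SNPs per window (default 15).
#' @param verbose Log dropped remainder SNPs.
#' @return A data frame of class `window_set`: `chrom`, `window` (global
#'   index), `chrom_window` (index within chromosome), `start_idx`/`end_idx`
#'   (locus column range in `gm`), `start`/`end` (bp span) and `n_snps`.
#' @export
make_windows <- function(gm, window_size = 15, verbose = TRUE) {
  stopifnot(window_size >= 2)
  chroms <- rle(gm$loci$chrom)
  offsets <- c(0L, cumsum(chroms$lengths))
  if (window_size > max(chroms$lengths)) {
    stop("window_size (", window_size,
         ") exceeds the SNP count of every chromosome")
  }
  out <- list()
  dropped <- 0L
  for (i in seq_along(chroms$values)) {
    n <- chroms$lengths[i]
    k <- n %/% window_size
    dropped <- dropped + (n - k * window_size)
    if (k == 0L) next
    s <- offsets[i] + (seq_len(k) - 1L) * window_size + 1L
    e <- s + window_size - 1L
    out[[i]] <- data.frame(
      chrom = chroms$values[i], chrom_window = seq_len(k),
      start_idx = s, end_idx = e,
      start = gm$loci$pos[s], end = gm$loci$pos[e],
      n_snps = window_size, stringsAsFactors = FALSE
    )
  }
  ws <- do.call(rbind, out)
  ws$window <- seq_len(nrow(ws))
  ws <- ws[, c("chrom", "window", "chrom_window", "start_idx", "end_idx",
               "start", "end", "n_snps")]
  if (verbose && dropped > 0) {
    message("make_windows: dropped ", dropped,
            " trailing remainder SNP(s) not filling a window")
  }
  class(ws) <- c("window_set", "data.frame")
  ws
}

# mean-impute missing calls per locus, then center per locus
impute_center <- function(calls) {
  mu <- colMeans(calls, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  x <- sweep(calls, 2, mu)
  x[is.na(x)] <- 0
  x
}

#' Summarize local relatedness structure in one window
#'
#' Missing genotypes are mean-imputed per locus, loci are centered, the
#' sample-by-sample covariance across the window's loci is formed and scaled
#' by its trace (so every window contributes unit total variance), and the
#' top-2 eigenpairs are retained as a rank-2 approximation.
#'
#' @param gm A [genotype_matrix()].
#' @param idx Integer vector of locus column indices forming the window.
#' @return An object of class `window_summary`: list with `values` (top-2
#'   eigenvalues of the trace-normalized covariance), `vectors` (n x 2
#'   orthonormal matrix), `total_variance` (trace before normalization),
#'   `n_samples` and `degenerate` (TRUE when the window carries no genotypic
#'   variance and cannot be summarized).
#' @export
window_summary <- function(gm, idx) {
  x <- impute_center(gm$calls[, idx, drop = FALSE])
  tot <- sum(x^2)
  n <- nrow(x)
  if (tot <= .Machine$double.eps * n) {
    return(structure(
      list(values = c(0, 0), vectors = matrix(0, n, 2),
           total_variance = 0, n_samples = n, degenerate = TRUE),
      class = "window_summary"
    ))
  }
  cv <- tcrossprod(x) / tot
  e <- eigen(cv, symmetric = TRUE)
  structure(
    list(values = pmax(e$values[1:2], 0), vectors = e$vectors[, 1:2, drop = FALSE],
         total_variance = tot, n_samples = n, degenerate = FALSE),
    class = "window_summary"
  )
}

#' Distance between two window summaries
#'
#' The Frobenius norm of the difference between the trace-normalized rank-2
#' covariance reconstructions, computed without forming the n x n matrices:
#' \deqn{\|A_2 - B_2\|_F^2 = \sum_i \lambda_{a,i}^2 + \sum_j \lambda_{b,j}^2
#'   - 2 \sum_{ij} \lambda_{a,i}\lambda_{b,j} (v_{a,i} \cdot v_{b,j})^2}
#' This is invariant to eigenvector sign flips and to rotations within
#' degenerate eigenspaces, unlike raw PC-coordinate differences.
#'
#' @param a,b `window_summary` objects over the same samples.
#' @return A single nonnegative distance.
#' @export
window_distance <- function(a, b) {
  if (a$n_samples != b$n_samples) {
    stop("window summaries come from different sample sets (",
         a$n_samples, " vs ", b$n_samples, " samples)")
  }
  cross <- crossprod(a$vectors, b$vectors)^2  # (v_ai . v_bj)^2
  d2 <- sum(a$values^2) + sum(b$values^2) -
    2 * as.numeric(t(a$values) %*% cross %*% b$values)
  sqrt(max(d2, 0))
}

#' Pairwise distance matrix between all windows
#'
#' Degenerate windows (no genotypic variance) are excluded with a log entry.
#'
#' @param gm A [genotype_matrix()].
#' @param ws A `window_set` from [make_windows()].
#' @param verbose Log excluded windows.
#' @return List with `d` (symmetric distance matrix over retained windows),
#'   `windows` (the retained subset of `ws`) and `summaries`.
#' @export
window_distance_matrix <- function(gm, ws, verbose = TRUE) {
  summaries <- lapply(seq_len(nrow(ws)), function(i) {
    window_summary(gm, ws$start_idx[i]:ws$end_idx[i])
  })
  ok <- !vapply(summaries, function(s) s$degenerate, logical(1))
  if (verbose && any(!ok)) {
    message("window_distance_matrix: excluded ", sum(!ok),
            " degenerate window(s) with no genotypic variance")
  }
  summaries <- summaries[ok]
  kept <- ws[ok, , drop = FALSE]
  m <- length(summaries)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d[i, j] <- d[j, i] <- window_distance(summaries[[i]], summaries[[j]])
    }
  }
  list(d = d, windows = kept, summaries = summaries)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns the leading `n_axes` coordinate axes scaled by the square root of
#' their eigenvalues. Negative eigenvalues among the requested axes are
#' truncated to zero with a warning. Each axis's sign is fixed so that its
#' largest-magnitude loading is positive, making output deterministic across
#' platforms.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal.
#' @param n_axes Number of MDS axes to return (default 4).
#' @return List of class `mds_embedding`: `points` (n x n_axes matrix with
#'   columns `MDS1..`) and `eig` (all eigenvalues of the double-centered
#'   matrix, descending).
#' @export
mds_embed <- function(d, n_axes = 4) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  stopifnot(n_axes >= 1, n_axes <= n - 1)
  b <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lam <- e$values[seq_len(n_axes)]
  if (any(lam < -1e-8 * max(abs(e$values), 1))) {
    warning("mds_embed: negative eigenvalue(s) among requested axes ",
            "truncated to zero; distances are not fully Euclidean")
  }
  lam <- pmax(lam, 0)
  pts <- e$vectors[, seq_len(n_axes), drop = FALSE] %*% diag(sqrt(lam), n_axes)
  # deterministic sign: largest-|loading| entry of each axis positive
  for (k in seq_len(n_axes)) {
    i <- which.max(abs(pts[, k]))
    if (length(i) && pts[i, k] < 0) pts[, k] <- -pts[, k]
  }
  colnames(pts) <- paste0("MDS", seq_len(n_axes))
  structure(list(points = pts, eig = e$values), class = "mds_embedding")
}

#' Window table with MDS coordinates
#'
#' Convenience wrapper producing the per-window report: chromosome, window
#' index, bp span, SNP count and MDS1..MDSk coordinates.
#'
#' @param gm A [genotype_matrix()].
#' @param ws A `window_set`.
#' @param n_axes MDS axes (default 4).
#' @param verbose Passed through.
#' @return Data frame with one row per retained window.
#' @export
local_pca_mds <- function(gm, ws, n_axes = 4, verbose = TRUE) {
  wd <- window_distance_matrix(gm, ws, verbose = verbose)
  emb <- mds_embed(wd$d, n_axes = n_axes)
  cbind(wd$windows, as.data.frame(emb$points))
}
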