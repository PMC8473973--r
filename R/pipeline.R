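#' Run the genome scan for candidate structural-variant regions
#'
#' End-to-end scan: read genotypes, window the genome, summarize local PCA
#' structure per window, embed between-window distances with classical MDS,
#' flag Tukey-fence outlier windows per axis, and call candidate regions.
#' A run with zero candidate regions is a successful (negative) result.
#'
#' @param input A VCF path or a [genotype_matrix()].
#' @param window_size SNPs per window (default 15).
#' @param mds_axes Number of MDS axes scanned (default 4).
#' @param min_outliers A region needs strictly more than this many outlier
#'   windows (default 4). Note a region of `L` SNPs can occupy at most
#'   `ceiling(L / window_size) + 1` windows, so to detect regions expected
#'   to hold few SNPs, choose `window_size` such that
#'   `L / window_size > min_outliers + 1` (e.g. `window_size = 5` for a
#'   ~26-SNP region) rather than relaxing the outlier count; at that
#'   resolution a real region occupies adjacent windows, so
#'   `max_gap_windows = 0` suppresses chance pairings of isolated noise
#'   outliers.
#' @param max_gap_windows Gap tolerance inside an outlier run (default 5).
#' @param min_maf,max_missing Locus filters applied when `input` is a VCF
#'   path (defaults 0.05 and 1).
#' @param out_dir Optional output directory for TSV/BED reports; each file
#'   carries a header comment with the tool version and resolved
#'   parameters.
#' @param verbose Log filter counts (default `TRUE`).
#' @return List of class `invscan_scan`: `gm`, `windows`, `mds` (window
#'   table with MDS coordinates), `outliers`, `regions`, `params`.
#' @export
run_scan <- function(input, window_size = 15, mds_axes = 4,
                     min_outliers = 4, max_gap_windows = 5,
                     min_maf = 0.05, max_missing = 1,
                     out_dir = NULL, verbose = TRUE) {
  params <- list(
    window_size = window_size, mds_axes = mds_axes,
    min_outliers = min_outliers, max_gap_windows = max_gap_windows,
    min_maf = min_maf, max_missing = max_missing
  )
  bad <- c(
    if (window_size < 2) "window_size must be >= 2",
    if (mds_axes < 1) "mds_axes must be >= 1",
    if (min_outliers < 0) "min_outliers must be >= 0",
    if (max_gap_windows < 0) "max_gap_windows must be >= 0",
    if (min_maf < 0 || min_maf >= 0.5) "min_maf must be in [0, 0.5)",
    if (max_missing < 0 || max_missing > 1) "max_missing must be in [0, 1]"
  )
  if (length(bad)) stop("invalid scan parameters:\n  ",
                        paste(bad, collapse = "\n  "))
  gm <- if (inherits(input, "genotype_matrix")) input else {
    read_vcf(input, min_maf = min_maf, max_missing = max_missing,
             verbose = verbose)
  }
  ws <- make_windows(gm, window_size = window_size, verbose = verbose)
  mds_tab <- local_pca_mds(gm, ws, n_axes = mds_axes, verbose = verbose)
  outliers <- mds_outliers(mds_tab)
  regions <- call_candidate_regions(outliers, min_outliers = min_outliers,
                                    max_gap_windows = max_gap_windows)
  res <- structure(
    list(gm = gm, windows = ws, mds = mds_tab, outliers = outliers,
         regions = regions, params = params),
    class = "invscan_scan"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(mds_tab, file.path(out_dir, "windows_mds.tsv"), params)
    write_report_tsv(outliers, file.path(out_dir, "outliers.tsv"), params)
    write_report_tsv(as.data.frame(regions),
                     file.path(out_dir, "regions.tsv"), params)
    if (nrow(regions)) {
      write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    }
  }
  res
}

#' @export
print.invscan_scan <- function(x, ...) {
  cat(sprintf("<invscan_scan> %d windows, %d outlier flags, %d candidate region(s)\n",
              nrow(x$mds), sum(x$outliers$is_outlier), nrow(x$regions)))
  if (nrow(x$regions)) print(as.data.frame(x$regions))
  invisible(x)
}

# TSV with a provenance header: tool version + resolved parameters
write_report_tsv <- function(df, path, params) {
  hdr <- c(
    paste0("# invscan ", as.character(utils::packageVersion("invscan"))),
    paste0("# ", paste(names(params), unlist(params), sep = "=",
                       collapse = " "))
  )
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a candidate region as a structural variant
#'
#' Runs the confirmation battery on one region: region PCA and karyotype
#' clustering, per-individual heterozygosity, LD stratified by karyotype,
#' and the chromosome LD network. Four criteria make up the SV signature:
#' \enumerate{
#'   \item three PC1 clusters with central heterozygosity excess
#'     (karyotype assignment succeeds),
#'   \item mean heterozygosity of heterokaryotypes exceeds both homokaryote
#'     groups,
#'   \item pooled region LD at least `ld_ratio` times each
#'     within-homokaryote mean (groups with enough samples),
#'   \item an LD-network component overlapping the region.
#' }
#' The verdict is `"SV-consistent"` when all four hold, otherwise
#' `"sweep-like/ambiguous"`; regions with fewer than 5 polymorphic SNPs get
#' `"under-resolution"`.
#'
#' @param gm The full [genotype_matrix()].
#' @param chrom,start,end Region coordinates (1-based inclusive), e.g. from
#'   a [call_candidate_regions()] row.
#' @param edge_min_r2,min_degree LD-network filter parameters (defaults 0.4
#'   and 4).
#' @param min_group Minimum homokaryote group size for stratified LD
#'   (default 5).
#' @param ld_ratio Required pooled/within LD ratio (default 3).
#' @param out_dir Optional report directory.
#' @param verbose Logging.
#' @return List of class `invscan_validation`: `region`, `assignments`,
#'   `summary` (karyotype summary or `NULL`), `het_rate`, `stratified_ld`,
#'   `network`, `criteria` (named logical vector), `verdict`.
#' @export
run_validate <- function(gm, chrom, start, end, edge_min_r2 = 0.4,
                         min_degree = 4, min_group = 5, ld_ratio = 3,
                         out_dir = NULL, verbose = TRUE) {
  region <- list(chrom = chrom, start = start, end = end)
  region_gm <- subset_region(gm, chrom, start, end)
  criteria <- c(three_clusters = FALSE, het_ordering = FALSE,
                ld_contrast = FALSE, network_span = FALSE)
  if (n_loci(region_gm) == 0 ||
      sum(locus_maf(region_gm) > 0, na.rm = TRUE) < 5) {
    return(structure(
      list(region = region, assignments = NULL, summary = NULL,
           het_rate = NULL, stratified_ld = NULL, network = NULL,
           criteria = criteria, verdict = "under-resolution"),
      class = "invscan_validation"
    ))
  }
  coords <- region_pca(region_gm)
  assignments <- assign_karyotypes(coords, region_gm)
  assigned <- any(assignments$karyotype != "UNASSIGNED")
  criteria[["three_clusters"]] <- assigned
  summary <- NULL
  strat <- NULL
  if (assigned) {
    summary <- summarize_karyotypes(assignments)
    hm <- summary$het_means
    criteria[["het_ordering"]] <-
      isTRUE(hm[["HET"]] > hm[["REF_HOM"]]) &&
      isTRUE(hm[["HET"]] > hm[["ALT_HOM"]])
    strat <- withCallingHandlers(
      stratified_ld(region_gm, assignments, min_group = min_group),
      warning = function(w) {
        if (verbose) message(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    pooled <- strat$mean_r2[strat$group == "POOLED"]
    within <- strat$mean_r2[strat$group != "POOLED"]
    within <- within[!is.na(within)]
    criteria[["ld_contrast"]] <- length(within) > 0 &&
      all(pooled >= ld_ratio * within)
  }
  chrom_tab <- pairwise_ld(gm, loci_idx = which(gm$loci$chrom == chrom))
  net <- ld_network(chrom_tab, edge_min_r2 = edge_min_r2,
                    min_degree = min_degree)
  if (nrow(net$components)) {
    ov <- net$components$chrom == chrom &
      net$components$start <= end & net$components$end >= start
    criteria[["network_span"]] <- any(ov)
  }
  verdict <- if (all(criteria)) "SV-consistent" else "sweep-like/ambiguous"
  res <- structure(
    list(region = region, assignments = assignments, summary = summary,
         het_rate = individual_heterozygosity(region_gm),
         stratified_ld = strat, network = net, criteria = criteria,
         verdict = verdict),
    class = "invscan_validation"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    params <- list(chrom = chrom, start = start, end = end,
                   edge_min_r2 = edge_min_r2, min_degree = min_degree,
                   min_group = min_group, ld_ratio = ld_ratio)
    write_report_tsv(assignments, file.path(out_dir, "karyotypes.tsv"),
                     params)
    if (!is.null(strat)) {
      write_report_tsv(strat, file.path(out_dir, "stratified_ld.tsv"),
                       params)
    }
    writeLines(c(
      paste0("verdict: ", verdict),
      paste0(names(criteria), ": ", criteria)
    ), file.path(out_dir, "verdict.txt"))
  }
  res
}

#' @export
print.invscan_validation <- function(x, ...) {
  cat("<invscan_validation> region ", x$region$chrom, ":",
      x$region$start, "-", x$region$end, "\n", sep = "")
  for (nm in names(x$criteria)) {
    cat(sprintf("  %-14s %s\n", nm, ifelse(x$criteria[[nm]], "PASS", "fail")))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
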