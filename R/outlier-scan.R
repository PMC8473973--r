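#' Tukey boxplot outliers of a numeric vector
#'
#' Hinges are Tukey's hinges (the rule used by standard boxplot statistics,
#' via [stats::fivenum()]); the fences sit 1.5 interquartile ranges beyond
#' them and values strictly outside the fences are flagged.
#'
#' @param values Numeric vector of at least 5 values.
#' @param coef Fence multiplier (default 1.5, the boxplot convention).
#' @return Data frame: `value`, `is_outlier`, `fence_low`, `fence_high`.
#' @export
tukey_outliers <- function(values, coef = 1.5) {
  if (length(values) < 5) stop("need at least 5 values for stable fences")
  fn <- stats::fivenum(values, na.rm = TRUE)
  iqr <- fn[4] - fn[2]
  lo <- fn[2] - coef * iqr
  hi <- fn[4] + coef * iqr
  data.frame(
    value = values,
    is_outlier = values < lo | values > hi,
    fence_low = lo, fence_high = hi
  )
}

#' Flag outlier windows on every MDS axis
#'
#' Outliers are computed per axis over all windows genome-wide.
#'
#' @param mds_tab Data frame from [local_pca_mds()] (windows plus `MDS*`
#'   columns).
#' @return Long data frame: window columns plus `axis`, `value`,
#'   `is_outlier`, `fence_low`, `fence_high`.
#' @export
mds_outliers <- function(mds_tab) {
  axes <- grep("^MDS[0-9]+$", names(mds_tab), value = TRUE)
  base_cols <- setdiff(names(mds_tab), axes)
  out <- lapply(axes, function(ax) {
    oc <- tukey_outliers(mds_tab[[ax]])
    cbind(mds_tab[base_cols], axis = ax, oc)
  })
  do.call(rbind, out)
}

#' Call candidate structural-variant regions from MDS outlier windows
#'
#' Per axis and per chromosome, outlier windows are grouped into runs in
#' which at most `max_gap_windows` consecutive non-outlier windows may
#' intervene; a run containing strictly more than `min_outliers` outlier
#' windows becomes a candidate region. Region coordinates run from the
#' start position of the first outlier window to the end position of the
#' last outlier window of the run. Regions found on different axes are
#' reported separately and flagged when they physically overlap another
#' axis's region.
#'
#' @param outliers Data frame from [mds_outliers()].
#' @param min_outliers A run must contain more than this many outlier
#'   windows to be called (default 4, i.e. at least 5).
#' @param max_gap_windows Maximum number of consecutive non-outlier windows
#'   tolerated inside a run (default 5).
#' @return Data frame of class `candidate_regions`: `chrom`, `start`, `end`,
#'   `axis`, `n_outlier_windows`, `first_window`, `last_window` (global
#'   window indices), `overlaps_other_axis`.
#' @export
call_candidate_regions <- function(outliers, min_outliers = 4,
                                   max_gap_windows = 5) {
  regs <- list()
  for (ax in unique(outliers$axis)) {
    oa <- outliers[outliers$axis == ax, ]
    for (ch in unique(oa$chrom)) {
      oc <- oa[oa$chrom == ch, ]
      oc <- oc[order(oc$chrom_window), ]
      hit <- which(oc$is_outlier)
      if (length(hit) == 0) next
      # split into runs: gap = intervening non-outlier windows
      run_id <- cumsum(c(1, diff(hit) - 1 > max_gap_windows))
      for (r in split(hit, run_id)) {
        if (length(r) <= min_outliers) next
        regs[[length(regs) + 1]] <- data.frame(
          chrom = ch,
          start = oc$start[r[1]],
          end = oc$end[r[length(r)]],
          axis = ax,
          n_outlier_windows = length(r),
          first_window = oc$window[r[1]],
          last_window = oc$window[r[length(r)]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(regs) == 0) {
    out <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      axis = character(), n_outlier_windows = integer(),
      first_window = integer(), last_window = integer(),
      overlaps_other_axis = logical()
    )
    class(out) <- c("candidate_regions", "data.frame")
    return(out)
  }
  out <- do.call(rbind, regs)
  out$overlaps_other_axis <- vapply(seq_len(nrow(out)), function(i) {
    any(out$chrom == out$chrom[i] & out$axis != out$axis[i] &
          out$start <= out$end[i] & out$end >= out$start[i])
  }, logical(1))
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Export candidate regions as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based closed, so
#' `start` is decremented by one on export.
#'
#' @param regions A `candidate_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = paste0(regions$axis, "_", seq_len(nrow(regions)))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
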