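#' Remove high-signal outlier peaks
#'
#' Drops peaks whose `signalValue` lies strictly above the given percentile
#' of the signalValue distribution of the input (default: 90th). Extreme
#' right-tail enrichment values are more likely experimental artifacts than
#' biology, so they are removed before any cross-database comparison. The
#' percentile uses linear interpolation between order statistics
#' (`stats::quantile()` type 7); ties at the threshold are retained.
#'
#' The filter is meant to be applied to the pooled signal distribution of
#' one transcription factor in one database (all samples together); apply it
#' per group with `dplyr::group_by()` + `dplyr::group_modify()` or via
#' [run_compare()] if you want per-sample scope.
#'
#' @param peaks Tibble of peaks with a `signalValue` column.
#' @param percentile Percentile threshold in (0, 100); default 90.
#' @return The input tibble minus rows with `signalValue` above the
#'   threshold; row order preserved.
#' @examples
#' x <- tibble::tibble(signalValue = 1:10)
#' nrow(filter_signal_outliers(x))  # 9: value 10 exceeds the 90th percentile
#' @export
filter_signal_outliers <- function(peaks, percentile = 90) {
  stopifnot(is.data.frame(peaks), "signalValue" %in% names(peaks))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be a single number in (0, 100)")
  }
  if (nrow(peaks) == 0L) return(peaks)
  cutoff <- quantile(peaks$signalValue, percentile / 100, names = FALSE, type = 7)
  peaks[peaks$signalValue <= cutoff, , drop = FALSE]
}

#' Shrink peaks to fixed windows around their summits
#'
#' Replaces each peak by a window of `half_window` bp on either side of the
#' summit (201 bp total by default), clipped at the chromosome origin. This
#' absorbs the positional uncertainty of narrowPeak summits and prevents
#' merging from producing very wide regions. Records without a summit
#' (`peak == -1`) cannot be windowed; they are skipped with a warning.
#'
#' @param peaks Tibble of peaks (needs `chrom`, `start`, `end`,
#'   `signalValue`, `peak`; label columns `tf`/`cell`/`database` are carried
#'   through).
#' @param half_window Window half-width in bp (default 100).
#' @return Tibble of regions: `chrom`, `start`, `end`, `signalValue`,
#'   `summit` (absolute position), `n_merged = 1`, plus labels. The number
#'   of summit-less records skipped is attached as attribute
#'   `n_missing_summit`.
#' @export
summit_windows <- function(peaks, half_window = 100) {
  stopifnot(is.data.frame(peaks))
  if (!is.numeric(half_window) || half_window < 0) {
    abort("`half_window` must be a non-negative number")
  }
  half_window <- as.integer(half_window)
  labels <- intersect(c("tf", "cell", "database"), names(peaks))

  no_summit <- peaks$peak == -1L
  n_missing <- sum(no_summit)
  if (n_missing > 0L) {
    warn(paste0(n_missing, " record(s) without a summit (peak == -1) skipped"))
    peaks <- peaks[!no_summit, , drop = FALSE]
  }
  summit <- as.integer(peaks$start + peaks$peak)
  out <- tibble(
    chrom = peaks$chrom,
    start = pmax(summit - half_window, 0L),
    end = summit + half_window + 1L,
    signalValue = peaks$signalValue,
    summit = summit,
    n_merged = 1L
  )
  for (lb in labels) out[[lb]] <- peaks[[lb]]
  attr(out, "n_missing_summit") <- n_missing
  out
}

#' Merge overlapping summit windows into consensus regions
#'
#' Within one transcription factor and database, windows from different
#' samples that overlap by at least 1 bp describe the same binding event.
#' Each connected component of the overlap graph (overlap is transitive
#' along the chromosome) is collapsed into a single region spanning the
#' base-pair union of its members, with `signalValue` the arithmetic mean
#' of the inputs, summit the floored mean of the input summits, and
#' `n_merged` the component size. Windows that overlap nothing pass through
#' unchanged. Bookended windows (`[a,b)` and `[b,c)`) share no base and are
#' not merged.
#'
#' @param regions Tibble of regions as produced by [summit_windows()]. All
#'   rows should belong to the same tf/cell/database group.
#' @return Tibble of pairwise non-overlapping regions, sorted by
#'   chromosome and start.
#' @examples
#' r <- summit_windows(tibble::tibble(
#'   chrom = "chr1", start = c(0, 120), end = c(240, 360),
#'   signalValue = c(20, 8), peak = c(120, 80)
#' ))
#' merge_overlapping_windows(r)  # one region, signalValue 14
#' @export
merge_overlapping_windows <- function(regions) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) == 0L) return(regions)
  need <- c("chrom", "start", "end", "signalValue", "summit")
  stopifnot(all(need %in% names(regions)))
  if (!"n_merged" %in% names(regions)) regions$n_merged <- 1L
  labels <- intersect(c("tf", "cell", "database"), names(regions))
  for (lb in labels) {
    if (length(unique(regions[[lb]])) > 1L) {
      abort(paste0("regions span multiple values of '", lb,
                   "'; merge within one group at a time"))
    }
  }

  merged <- regions |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(g, key) merge_one_chrom(g)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
  for (lb in labels) merged[[lb]] <- regions[[lb]][1]
  merged
}

merge_one_chrom <- function(g) {
  ir <- bed_to_iranges(g$start, g$end)
  # min.gapwidth = 0 keeps bookended windows apart: only true >=1 bp
  # overlaps are unified, matching the overlap definition used everywhere.
  comp_ranges <- IRanges::reduce(ir, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(ir, comp_ranges)
  comp <- S4Vectors::subjectHits(hits)
  bed <- iranges_to_bed(comp_ranges)
  g |>
    mutate(.component = comp) |>
    group_by(.data$.component) |>
    summarise(
      start = bed$start[.data$.component[1]],
      end = bed$end[.data$.component[1]],
      # each merged component averages the *original* inputs in one shot,
      # weighting every window equally regardless of prior n_merged
      signalValue = mean(.data$signalValue),
      summit = as.integer(floor(mean(.data$summit))),
      n_merged = dplyr::n(),
      .groups = "drop"
    ) |>
    select(!".component")
}

#' Select transcription factors eligible for cross-database comparison
#'
#' A TF is comparable only when both databases assayed it in the same cell
#' line, and TFs with unusually many samples (heavily re-assayed,
#' non-tissue-specific factors) would dominate descriptive statistics, so
#' TFs exceeding `max_samples` samples in either database are excluded.
#'
#' @param samples Tibble with columns `tf`, `database`, `sample_id` (one or
#'   more rows per sample; typically stacked peaks from
#'   [read_peak_manifest()]).
#' @param max_samples Maximum sample count per TF per database (default 9).
#' @param databases Character vector of the databases that must all contain
#'   the TF; defaults to every database present in `samples`.
#' @return Sorted character vector of eligible TF names.
#' @export
select_eligible_tfs <- function(samples, max_samples = 9, databases = NULL) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) return(character())
  stopifnot(all(c("tf", "database", "sample_id") %in% names(samples)))
  if (is.null(databases)) databases <- unique(samples$database)

  counts <- samples |>
    dplyr::distinct(.data$tf, .data$database, .data$sample_id) |>
    count(.data$tf, .data$database, name = "n_samples")
  ok <- counts |>
    filter(.data$database %in% .env$databases) |>
    group_by(.data$tf) |>
    summarise(
      in_all = length(unique(.data$database)) == length(.env$databases),
      within_cap = all(.data$n_samples <= .env$max_samples),
      .groups = "drop"
    ) |>
    filter(.data$in_all, .data$within_cap)
  sort(ok$tf)
}

#' Preprocess one TF/database group of raw peaks into regions
#'
#' Convenience composition of the three preprocessing steps:
#' outlier filter on the pooled signal distribution, summit windowing, and
#' overlap merging.
#'
#' @inheritParams filter_signal_outliers
#' @inheritParams summit_windows
#' @param percentile Signal-filter percentile, or `NULL` to skip the filter
#'   (e.g. when it was already applied per sample).
#' @return List with `regions` (merged tibble) and `report` (one-row tibble
#'   of input/filter/merge counts).
#' @export
preprocess_peaks <- function(peaks, half_window = 100, percentile = 90) {
  n_input <- nrow(peaks)
  kept <- if (is.null(percentile)) peaks
    else filter_signal_outliers(peaks, percentile)
  windows <- summit_windows(kept, half_window)
  regions <- merge_overlapping_windows(windows)
  report <- tibble(
    n_input = n_input,
    n_filtered_outlier = n_input - nrow(kept),
    n_missing_summit = attr(windows, "n_missing_summit") %||% 0L,
    n_regions_out = nrow(regions),
    mean_width = if (nrow(regions)) mean(regions$end - regions$start) else NA_real_
  )
  list(regions = regions, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
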