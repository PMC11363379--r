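#' Read a BED narrowPeak file
#'
#' Parses a 10-column UCSC narrowPeak (BED6+4) file into a tibble of peaks.
#' Coordinates stay in BED convention: 0-based, half-open `[start, end)`.
#' Column 10 (`peak`) is the summit offset from `start`, or -1 when the
#' caller did not report a summit; such records are kept but flagged via
#' `has_summit` because downstream preprocessing needs summits.
#'
#' Lines starting with `#`, `track` or `browser` are skipped. Every record is
#' validated: `start < end`, `signalValue >= 0`, and `start + peak < end`
#' unless `peak == -1`. A violation is an error naming the offending line.
#'
#' @param path Path to a narrowPeak file.
#' @param tf,cell,database,sample_id Optional labels attached as columns,
#'   used to group peaks when several files are stacked.
#' @return A tibble with the ten narrowPeak columns plus `has_summit` and
#'   any labels supplied.
#' @examples
#' np <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t300\tp1\t0\t.\t20\t-1\t-1\t50", np)
#' read_narrowpeak(np)
#' @export
read_narrowpeak <- function(path, tf = NULL, cell = NULL, database = NULL,
                            sample_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("narrowPeak file not found: ", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = integer(), strand = character(),
      signalValue = double(), pValue = double(), qValue = double(),
      peak = integer(), has_summit = logical()
    )
    return(add_peak_labels(out, tf, cell, database, sample_id))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- line_no[which(nf < 10L)[1]]
    abort(paste0(
      "line ", bad, " of ", path, " has ", nf[which(nf < 10L)[1]],
      " columns; narrowPeak needs 10 (is this a plain BED file?)"
    ))
  }
  if (any(nf > 10L)) {
    bad <- line_no[which(nf > 10L)[1]]
    abort(paste0("line ", bad, " of ", path, " has more than 10 columns"))
  }

  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  suppressWarnings({
    start <- as.integer(m[, 2])
    end <- as.integer(m[, 3])
    score <- as.integer(m[, 5])
    signal <- as.numeric(m[, 7])
    pval <- as.numeric(m[, 8])
    qval <- as.numeric(m[, 9])
    peak <- as.integer(m[, 10])
  })

  fail <- function(cond, msg) {
    i <- which(cond)[1]
    if (length(i) && !is.na(i)) {
      abort(paste0("line ", line_no[i], " of ", path, ": ", msg))
    }
  }
  fail(is.na(start) | is.na(end), "non-integer start/end")
  fail(is.na(signal), "non-numeric signalValue")
  fail(is.na(peak), "non-integer peak (summit offset)")
  fail(start >= end, "start >= end")
  fail(signal < 0, "negative signalValue")
  fail(peak != -1L & (peak < 0L | start + peak >= end),
       "summit offset outside [start, end)")

  out <- tibble(
    chrom = m[, 1], start = start, end = end, name = m[, 4],
    score = score, strand = m[, 6], signalValue = signal,
    pValue = pval, qValue = qval, peak = peak,
    has_summit = peak != -1L
  )
  add_peak_labels(out, tf, cell, database, sample_id)
}

add_peak_labels <- function(x, tf, cell, database, sample_id) {
  if (!is.null(tf)) x$tf <- tf
  if (!is.null(cell)) x$cell <- cell
  if (!is.null(database)) x$database <- database
  if (!is.null(sample_id)) x$sample_id <- sample_id
  x
}

#' Write regions (or peaks) as a BED narrowPeak file
#'
#' Serializes a tibble of post-preprocessing regions, or raw peaks, back to
#' the 10-column narrowPeak format. For regions the summit is written as
#' column 10 (offset from start), score is 0, strand ".", and p/q-values -1.
#' `signalValue` is written with 4 decimal places, so a write/read round
#' trip reproduces it to that precision.
#'
#' @param regions Tibble with at least `chrom`, `start`, `end`,
#'   `signalValue`, and either `summit` (absolute position) or `peak`
#'   (offset).
#' @param path Output file path.
#' @return `path`, invisibly usable in pipes.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  peak_off <- if ("summit" %in% names(regions)) {
    as.integer(regions$summit - regions$start)
  } else if ("peak" %in% names(regions)) {
    as.integer(regions$peak)
  } else {
    rep(-1L, nrow(regions))
  }
  lines <- paste(
    regions$chrom,
    as.integer(regions$start),
    as.integer(regions$end),
    if ("name" %in% names(regions)) regions$name
      else sprintf("region_%d", seq_len(nrow(regions))),
    if ("score" %in% names(regions)) as.integer(regions$score) else 0L,
    if ("strand" %in% names(regions)) regions$strand else ".",
    sprintf("%.4f", regions$signalValue),
    if ("pValue" %in% names(regions)) regions$pValue else -1,
    if ("qValue" %in% names(regions)) regions$qValue else -1,
    peak_off,
    sep = "\t"
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a plain BED interval file
#'
#' Reads the first three columns (chrom, start, end) of a BED file, e.g. a
#' HOT/blacklist track. Intervals are merged on load (union of overlapping
#' or bookended intervals per chromosome) so the result is internally
#' non-overlapping, as the overlap-fraction computations require.
#'
#' @param path Path to a BED file with >= 3 columns.
#' @param merge Merge overlapping intervals on load (default TRUE).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path, merge = TRUE) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) abort(paste0(path, ": BED needs >= 3 columns"))
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L))
  )
  if (any(is.na(out$start) | is.na(out$end)) || any(out$start >= out$end)) {
    abort(paste0(path, ": malformed BED interval"))
  }
  if (merge) merge_bed_intervals(out) else out
}

# Union of intervals per chromosome; bookended intervals are fused too
# (coverage is unchanged either way).
merge_bed_intervals <- function(x) {
  x |>
    group_by(.data$chrom) |>
    dplyr::reframe(iranges_to_bed(IRanges::reduce(bed_to_iranges(.data$start, .data$end)))) |>
    arrange(.data$chrom, .data$start) |>
    as_tibble()
}

#' Read a peak manifest and load all referenced narrowPeak files
#'
#' The manifest is a TSV with columns `path`, `database`, `cell`, `tf`,
#' `sample_id`; relative paths are resolved against the manifest's
#' directory. All files are read with [read_narrowpeak()] and stacked into
#' one tibble.
#'
#' @param path Path to the manifest TSV.
#' @return Tibble of labelled peaks from all samples.
#' @export
read_peak_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("path", "database", "cell", "tf", "sample_id")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    abort(paste0("manifest lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  root <- dirname(path)
  purrr::pmap(man[need], function(path, database, cell, tf, sample_id) {
    f <- if (file.exists(path)) path else file.path(root, path)
    if (!file.exists(f)) {
      abort(paste0("manifest row for sample '", sample_id, "': file not found: ", path))
    }
    read_narrowpeak(f, tf = tf, cell = cell, database = database,
                    sample_id = as.character(sample_id))
  }) |>
    bind_rows()
}
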