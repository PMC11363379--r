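bin_levels <- c("L", "M", "H")

#' Rank-bin regions by signalValue into low/medium/high tiers
#'
#' Splits the signalValue distribution of one database's post-merge regions
#' into three rank bins: L (bottom quarter), M (middle half), H (top
#' quarter), a 1:2:1 ratio. Binning by rank forgets the raw signal scale,
#' which makes signal tiers comparable across databases whose pipelines
#' produce very different signalValue magnitudes. Quantiles use linear
#' interpolation (type 7); ties at a boundary are pushed downward, so H is
#' strictly above the upper quantile. With heavy ties the realized ratio
#' degrades (degenerate case: all signals equal gives all L); inspect the
#' realized fractions with `table(out$bin)`.
#'
#' @param regions Tibble with a `signalValue` column.
#' @param q_low,q_high Quantile boundaries (defaults 0.25 and 0.75).
#' @return The input with an added ordered factor column `bin`
#'   (levels L < M < H).
#' @export
assign_signal_bins <- function(regions, q_low = 0.25, q_high = 0.75) {
  stopifnot(is.data.frame(regions), "signalValue" %in% names(regions))
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    abort("need 0 < q_low < q_high < 1")
  }
  if (nrow(regions) == 0L) {
    regions$bin <- factor(character(), levels = bin_levels, ordered = TRUE)
    return(regions)
  }
  if (nrow(regions) < 4L) {
    warn("fewer than 4 regions: signal quantiles are unstable")
  }
  qs <- quantile(regions$signalValue, c(q_low, q_high), names = FALSE, type = 7)
  s <- regions$signalValue
  lab <- ifelse(s <= qs[1], "L", ifelse(s > qs[2], "H", "M"))
  regions$bin <- factor(lab, levels = bin_levels, ordered = TRUE)
  regions
}

#' Genometric overlap join of two region sets
#'
#' Pairs every region of A with every region of B it shares at least 1 bp
#' with (half-open intervals: bookended regions do not pair). The join is
#' many-to-many — a wide A region overlapping two B regions yields two
#' matched pairs — and records the overlap width and, when present, both
#' regions' signal bins.
#'
#' @param set_a,set_b Tibbles of internally non-overlapping regions
#'   (`chrom`, `start`, `end`; optionally `signalValue`, `bin`).
#' @return Tibble of matched pairs: `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `overlap_bp`, plus `signal_a`/`signal_b` and `bin_a`/`bin_b`
#'   when available.
#' @export
genometric_join <- function(set_a, set_b) {
  check_nonoverlapping(set_a, "set_a")
  check_nonoverlapping(set_b, "set_b")
  chroms <- intersect(unique(set_a$chrom), unique(set_b$chrom))
  pairs <- purrr::map(chroms, function(ch) {
    ga <- set_a[set_a$chrom == ch, , drop = FALSE]
    gb <- set_b[set_b$chrom == ch, , drop = FALSE]
    ir_a <- bed_to_iranges(ga$start, ga$end)
    ir_b <- bed_to_iranges(gb$start, gb$end)
    hits <- IRanges::findOverlaps(ir_a, ir_b, minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out <- tibble(
      chrom = ch,
      start_a = ga$start[qi], end_a = ga$end[qi],
      start_b = gb$start[si], end_b = gb$end[si],
      overlap_bp = as.integer(pmin(ga$end[qi], gb$end[si]) -
                              pmax(ga$start[qi], gb$start[si]))
    )
    if ("signalValue" %in% names(ga)) out$signal_a <- ga$signalValue[qi]
    if ("signalValue" %in% names(gb)) out$signal_b <- gb$signalValue[si]
    if ("bin" %in% names(ga)) out$bin_a <- ga$bin[qi]
    if ("bin" %in% names(gb)) out$bin_b <- gb$bin[si]
    out
  })
  out <- bind_rows(pairs)
  if (nrow(out) == 0L) {
    out <- tibble(
      chrom = character(), start_a = integer(), end_a = integer(),
      start_b = integer(), end_b = integer(), overlap_bp = integer()
    )
    if ("bin" %in% names(set_a)) out$bin_a <- factor(character(), bin_levels, ordered = TRUE)
    if ("bin" %in% names(set_b)) out$bin_b <- factor(character(), bin_levels, ordered = TRUE)
  }
  arrange(out, .data$chrom, .data$start_a, .data$start_b)
}

#' Left outer genometric match: which A regions does B confirm?
#'
#' Flags each region of `set_a` as matched iff it overlaps at least one
#' region of `set_b` (>= 1 bp). The recall — matched fraction of A — and the
#' size ratio |A|/|B| are attached as attributes and reported by
#' [match_stats()].
#'
#' @inheritParams genometric_join
#' @return `set_a` with a logical `matched` column; attributes `recall` and
#'   `size_ratio`.
#' @export
left_outer_match <- function(set_a, set_b) {
  check_nonoverlapping(set_a, "set_a")
  check_nonoverlapping(set_b, "set_b")
  if (nrow(set_b) == 0L) abort("set_b is empty: size ratio undefined")
  matched <- rep(FALSE, nrow(set_a))
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ia <- which(set_a$chrom == ch)
    gb <- set_b[set_b$chrom == ch, , drop = FALSE]
    cnt <- IRanges::countOverlaps(
      bed_to_iranges(set_a$start[ia], set_a$end[ia]),
      bed_to_iranges(gb$start, gb$end),
      minoverlap = 1L
    )
    matched[ia] <- cnt > 0L
  }
  out <- mutate(set_a, matched = matched)
  attr(out, "recall") <- if (nrow(set_a)) mean(matched) else NA_real_
  attr(out, "size_ratio") <- nrow(set_a) / nrow(set_b)
  attr(out, "n_b") <- nrow(set_b)
  out
}

#' Summary statistics of a left outer match
#'
#' @param matched_a Result of [left_outer_match()].
#' @return One-row tibble: `n_a`, `n_b`, `n_matched`, `recall`,
#'   `size_ratio`.
#' @export
match_stats <- function(matched_a) {
  stopifnot("matched" %in% names(matched_a))
  sr <- attr(matched_a, "size_ratio")
  tibble(
    n_a = nrow(matched_a),
    n_b = attr(matched_a, "n_b") %||% NA_integer_,
    n_matched = sum(matched_a$matched),
    recall = if (nrow(matched_a)) mean(matched_a$matched) else NA_real_,
    size_ratio = sr %||% NA_real_
  )
}

#' Joint signal-bin contingency of matched pairs
#'
#' Cross-tabulates the (bin A, bin B) labels of overlapping pairs into a
#' 3x3 contingency and compares the observed joint probabilities to the
#' expectation under independence. Counting is pair-level: a region
#' participating in several pairs contributes once per pair.
#'
#' Under the nominal null the marginals are the design fractions
#' (0.25, 0.50, 0.25) in each database and the expected joint probability is
#' their outer product, e.g. P(H, H) = 0.0625; a ratio above 1 in the (H, H)
#' cell means high-signal sites co-occur across databases more often than
#' independence predicts. `marginals = "empirical"` instead uses the
#' realized bin fractions among the matched pairs themselves, which absorbs
#' tie-induced distortions of the 1:2:1 design.
#'
#' @param pairs Tibble of matched pairs with `bin_a`, `bin_b` (from
#'   [genometric_join()]).
#' @param marginals `"nominal"` (default) or `"empirical"` null marginals.
#' @param level Count `"pairs"` (default) or `"regions"` (distinct A-side
#'   regions, classified by their own bin and the bin of each partner —
#'   region-level counting deduplicates identical (coordinates, bins) rows).
#' @return A `bin_contingency` object: list with `counts`, `observed`,
#'   `expected`, `ratio` (3x3 matrices), `total`, `marginals`. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
bin_contingency <- function(pairs, marginals = c("nominal", "empirical"),
                            level = c("pairs", "regions")) {
  marginals <- match.arg(marginals)
  level <- match.arg(level)
  stopifnot(is.data.frame(pairs), all(c("bin_a", "bin_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) abort("no matched pairs: contingency undefined")
  if (level == "regions") {
    pairs <- dplyr::distinct(pairs, .data$chrom, .data$start_a, .data$end_a,
                             .data$bin_a, .data$bin_b)
  }
  fa <- factor(pairs$bin_a, levels = bin_levels)
  fb <- factor(pairs$bin_b, levels = bin_levels)
  counts <- table(fa, fb)
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(A = bin_levels, B = bin_levels))
  total <- sum(counts)
  observed <- counts / total
  expected <- switch(marginals,
    nominal = outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)),
    empirical = outer(rowSums(observed), colSums(observed))
  )
  dimnames(expected) <- dimnames(counts)
  ratio <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(
    list(counts = counts, observed = observed, expected = expected,
         ratio = ratio, total = total, marginals = marginals, level = level),
    class = "bin_contingency"
  )
}

#' @export
print.bin_contingency <- function(x, ...) {
  cat("Signal-bin contingency (", x$total, " ", x$level,
      ", ", x$marginals, " null)\n\n", sep = "")
  cat("observed/expected ratio:\n")
  print(round(x$ratio, 3))
  invisible(x)
}

#' @describeIn bin_contingency One row per (bin A, bin B) cell with count,
#'   observed and expected probability, and their ratio.
#' @param x A `bin_contingency` object.
#' @param ... Unused.
#' @export
tidy.bin_contingency <- function(x, ...) {
  grid <- expand.grid(bin_a = bin_levels, bin_b = bin_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble(
    bin_a = grid$bin_a, bin_b = grid$bin_b,
    count = as.integer(x$counts[cbind(grid$bin_a, grid$bin_b)]),
    observed = x$observed[cbind(grid$bin_a, grid$bin_b)],
    expected = x$expected[cbind(grid$bin_a, grid$bin_b)],
    ratio = x$ratio[cbind(grid$bin_a, grid$bin_b)]
  ) |>
    arrange(factor(.data$bin_a, bin_levels), factor(.data$bin_b, bin_levels))
}

#' @describeIn bin_contingency One-row summary: pair total, the (H,H) and
#'   (L,L) ratios, and Pearson's chi-squared statistic against the null.
#' @export
glance.bin_contingency <- function(x, ...) {
  exp_counts <- x$expected * x$total
  chisq <- sum((x$counts - exp_counts)^2 / exp_counts)
  tibble(
    total = x$total,
    ratio_HH = x$ratio["H", "H"],
    ratio_LL = x$ratio["L", "L"],
    chisq = chisq,
    marginals = x$marginals
  )
}

#' @describeIn bin_contingency Heatmap of observed/expected ratios
#'   (log2 colour scale).
#' @param object A `bin_contingency` object.
#' @export
autoplot.bin_contingency <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_b, y = .data$bin_a,
                                  fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ratio))) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 obs/exp") +
    ggplot2::labs(x = "signal bin, database B", y = "signal bin, database A",
                  title = "Joint signal-bin enrichment of matched regions")
}
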