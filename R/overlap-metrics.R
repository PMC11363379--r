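#' Base-pair overlap counts between two region sets
#'
#' Counts, genome-wide, the base pairs covered by both sets (`a`), by set A
#' only (`b`), and by set B only (`c`), summed over chromosomes. These
#' presence/absence counts over bases are the raw material for all the
#' similarity coefficients. Both inputs must already be internally
#' non-overlapping (i.e. post-merge regions); an overlapping input is a
#' contract error, because `b` and `c` would double-count bases.
#'
#' @param set_a,set_b Tibbles of regions with `chrom`, `start`, `end`.
#' @return One-row tibble: `a`, `b`, `c`, `n` (= a+b+c), `bp_a`, `bp_b`
#'   (total coverage of each set).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_counts(a, b)  # a = b = c = 50
#' @export
overlap_counts <- function(set_a, set_b) {
  check_nonoverlapping(set_a, "set_a")
  check_nonoverlapping(set_b, "set_b")
  chroms <- union(unique(set_a$chrom), unique(set_b$chrom))
  acc <- c(a = 0, b = 0, c = 0)
  for (ch in chroms) {
    ir_a <- with(set_a[set_a$chrom == ch, ], bed_to_iranges(start, end))
    ir_b <- with(set_b[set_b$chrom == ch, ], bed_to_iranges(start, end))
    acc["a"] <- acc["a"] + sum(IRanges::width(IRanges::intersect(ir_a, ir_b)))
    acc["b"] <- acc["b"] + sum(IRanges::width(IRanges::setdiff(ir_a, ir_b)))
    acc["c"] <- acc["c"] + sum(IRanges::width(IRanges::setdiff(ir_b, ir_a)))
  }
  tibble(
    a = acc[["a"]], b = acc[["b"]], c = acc[["c"]],
    n = sum(acc),
    bp_a = acc[["a"]] + acc[["b"]],
    bp_b = acc[["a"]] + acc[["c"]]
  )
}

check_nonoverlapping <- function(x, label) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) < 2L) return(invisible(x))
  bad <- x |>
    group_by(.data$chrom) |>
    summarise(
      ok = sum(.data$end - .data$start) ==
        sum(IRanges::width(IRanges::reduce(bed_to_iranges(.data$start, .data$end),
                                           min.gapwidth = 0L))),
      .groups = "drop"
    )
  if (!all(bad$ok)) {
    abort(paste0("`", label, "` contains internally overlapping regions; ",
                 "run merge_overlapping_windows() first"))
  }
  invisible(x)
}

#' General (base-pair) Jaccard index
#'
#' Intersection over union of covered bases: `a / (a + b + c)`. Sensitive to
#' set-size imbalance — a perfect subset of a much larger set still scores
#' low — which is why the Forbes coefficient is reported alongside.
#'
#' @param counts Data frame with columns `a`, `b`, `c` (one or more rows,
#'   e.g. from [overlap_counts()]).
#' @return Numeric vector of Jaccard indices in \[0, 1\], one per row.
#' @export
jaccard_general <- function(counts) {
  abc <- check_counts(counts)
  n <- abc$a + abc$b + abc$c
  if (any(n == 0)) abort("both sets empty (a + b + c == 0): Jaccard undefined")
  abc$a / n
}

#' Conditional (one-sided) Jaccard index
#'
#' Overlap divided by one side's coverage only: `a / (a + b)` for side A,
#' `a / (a + c)` for side B. The closer to 1, the more fully that side is
#' recalled by the other set's regions.
#'
#' @inheritParams jaccard_general
#' @param side `"A"` or `"B"`: whose coverage is the denominator.
#' @return Numeric vector in \[0, 1\].
#' @export
jaccard_conditional <- function(counts, side = c("A", "B")) {
  side <- match.arg(side)
  abc <- check_counts(counts)
  denom <- if (side == "A") abc$a + abc$b else abc$a + abc$c
  if (any(denom == 0)) {
    abort(paste0("side ", side, " has zero coverage: conditional Jaccard undefined"))
  }
  abc$a / denom
}

#' Alroy-corrected Forbes coefficient
#'
#' A size-robust binary similarity over base-pair presence/absence counts:
#' \deqn{F' = \frac{a(n + \sqrt{n})}{(a+b)(a+c) + a\sqrt{n} + \frac{1}{2} b c}}
#' with `n = a + b + c`. Unlike the Jaccard index it is far less depressed
#' when one set is much larger than the other; it equals 1 when the sets
#' coincide and 0 when they are disjoint.
#'
#' @inheritParams jaccard_general
#' @return Numeric vector of coefficients, one per row.
#' @export
alroy_forbes <- function(counts) {
  abc <- check_counts(counts)
  a <- abc$a; b <- abc$b; cc <- abc$c
  n <- a + b + cc
  if (any(n == 0)) abort("both sets empty (a + b + c == 0): Forbes undefined")
  denom <- (a + b) * (a + cc) + a * sqrt(n) + 0.5 * b * cc
  if (any(denom == 0)) {
    abort("degenerate counts (a == 0 and an empty side): Forbes undefined")
  }
  a * (n + sqrt(n)) / denom
}

check_counts <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("a", "b", "c") %in% names(counts)))
  abc <- counts[c("a", "b", "c")]
  if (any(unlist(abc) < 0)) abort("overlap counts must be non-negative")
  abc
}

#' All overlap coefficients for one pair of region sets
#'
#' Runs [overlap_counts()] and appends the general Jaccard index, both
#' conditional Jaccard indices and the Alroy-corrected Forbes coefficient —
#' one row of the per-TF metrics table.
#'
#' @inheritParams overlap_counts
#' @return One-row tibble: counts plus `jaccard_general`, `jaccard_cond_A`,
#'   `jaccard_cond_B`, `alroy_forbes`.
#' @export
overlap_metrics <- function(set_a, set_b) {
  oc <- overlap_counts(set_a, set_b)
  oc |>
    mutate(
      jaccard_general = if (oc$n > 0) jaccard_general(oc) else NA_real_,
      jaccard_cond_A = if (oc$bp_a > 0) jaccard_conditional(oc, "A") else NA_real_,
      jaccard_cond_B = if (oc$bp_b > 0) jaccard_conditional(oc, "B") else NA_real_,
      alroy_forbes = if (oc$n > 0 && (oc$a > 0 || (oc$b > 0 && oc$c > 0)))
        alroy_forbes(oc) else NA_real_
    )
}
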