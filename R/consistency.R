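#' Conditional signal distribution given a high-signal match
#'
#' Restricts the matched pairs to those whose chosen side carries the H
#' (top-quarter) bin and tabulates the other side's bin distribution among
#' them. Under independence of matching and signal this distribution equals
#' the design marginals (0.25, 0.50, 0.25); an excess of H answers the core
#' question — does a site matching a high-signal site tend to be
#' high-signal itself?
#'
#' @param pairs Matched pairs with `bin_a`, `bin_b` ([genometric_join()]).
#' @param side `"B"` (default): condition on B being high and return the
#'   distribution of A's bins; `"A"`: the converse.
#' @return A `conditional_distribution` object: `condition` label, `probs`
#'   (named numeric over L/M/H, NA when `n == 0`), `null_probs`, `n`.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
conditional_given_high <- function(pairs, side = c("B", "A")) {
  side <- match.arg(side)
  stopifnot(is.data.frame(pairs), all(c("bin_a", "bin_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) abort("no matched pairs supplied")
  cond_col <- if (side == "B") "bin_b" else "bin_a"
  other_col <- if (side == "B") "bin_a" else "bin_b"
  sel <- pairs[pairs[[cond_col]] == "H", , drop = FALSE]
  n <- nrow(sel)
  probs <- if (n > 0L) {
    tab <- table(factor(sel[[other_col]], levels = bin_levels))
    setNames(as.numeric(tab) / n, bin_levels)
  } else {
    warn(paste0("no pairs with ", cond_col, " == H; probabilities undefined"))
    setNames(rep(NA_real_, 3L), bin_levels)
  }
  structure(
    list(
      condition = paste0(side, " == H"),
      probs = probs,
      null_probs = setNames(c(0.25, 0.5, 0.25), bin_levels),
      n = n
    ),
    class = "conditional_distribution"
  )
}

#' @export
print.conditional_distribution <- function(x, ...) {
  cat("Conditional signal-bin distribution given ", x$condition,
      " (n = ", x$n, ")\n", sep = "")
  print(round(x$probs, 4))
  invisible(x)
}

#' @describeIn conditional_given_high One row per bin with conditional and
#'   null probability.
#' @param x A `conditional_distribution` object.
#' @param ... Unused.
#' @export
tidy.conditional_distribution <- function(x, ...) {
  tibble(
    bin = bin_levels,
    prob = unname(x$probs[bin_levels]),
    null_prob = unname(x$null_probs[bin_levels])
  )
}

#' @describeIn conditional_given_high One-row summary with the conditioning
#'   side, pair count and the H-bin excess over the null.
#' @export
glance.conditional_distribution <- function(x, ...) {
  tibble(
    condition = x$condition,
    n = x$n,
    prob_H = unname(x$probs["H"]),
    excess_H = unname(x$probs["H"] - x$null_probs["H"])
  )
}

#' @describeIn conditional_given_high Bar chart of the conditional
#'   distribution with the independence null overlaid.
#' @param object A `conditional_distribution` object.
#' @export
autoplot.conditional_distribution <- function(object, ...) {
  d <- tidy(object)
  d$bin <- factor(d$bin, bin_levels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_prob), colour = "red", size = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_prob, group = 1),
                       colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "signal bin", y = "conditional probability",
      title = paste0("P(bin | ", object$condition, "), red = independence null"),
      subtitle = paste0("n = ", object$n, " conditioning pairs")
    )
}

#' Fraction of bound bases falling in HOT regions, by stratum
#'
#' High-occupancy-target (HOT) / blacklist regions attract ChIP signal
#' without genuine binding, so the fraction of a region set's base pairs
#' that land in HOT territory gauges how artifact-prone the set is. The
#' fraction is computed for all regions pooled, per signal bin, and — when
#' a `matched` flag is present (see [left_outer_match()]) — for the matched
#' subset overall and per bin. An empty stratum reports `NA`, never 0.
#'
#' @param regions Tibble of non-overlapping regions, optionally with `bin`
#'   and `matched` columns.
#' @param hot Tibble of HOT intervals (`chrom`, `start`, `end`); merged
#'   internally so overlap accounting is exact.
#' @return Tibble: `stratum`, `bp_total`, `bp_in_hot`, `fraction`.
#' @export
hot_overlap_fraction <- function(regions, hot) {
  check_nonoverlapping(regions, "regions")
  stopifnot(is.data.frame(hot), all(c("chrom", "start", "end") %in% names(hot)))
  hot <- merge_bed_intervals(hot)

  strata <- list(all = rep(TRUE, nrow(regions)))
  if ("bin" %in% names(regions)) {
    for (b in bin_levels) strata[[b]] <- regions$bin == b
  }
  if ("matched" %in% names(regions)) {
    strata$matched <- regions$matched
    if ("bin" %in% names(regions)) {
      for (b in bin_levels) {
        strata[[paste0("matched_", b)]] <- regions$matched & regions$bin == b
      }
    }
  }

  purrr::imap(strata, function(sel, nm) {
    sub <- regions[sel, , drop = FALSE]
    bp_total <- sum(sub$end - sub$start)
    bp_in_hot <- 0
    for (ch in intersect(unique(sub$chrom), unique(hot$chrom))) {
      ir_r <- with(sub[sub$chrom == ch, ], bed_to_iranges(start, end))
      ir_h <- with(hot[hot$chrom == ch, ], bed_to_iranges(start, end))
      bp_in_hot <- bp_in_hot + sum(IRanges::width(IRanges::intersect(ir_r, ir_h)))
    }
    tibble(
      stratum = nm,
      bp_total = bp_total,
      bp_in_hot = bp_in_hot,
      fraction = if (bp_total > 0) bp_in_hot / bp_total else NA_real_
    )
  }) |>
    bind_rows()
}

#' Assemble the per-TF summary row
#'
#' Joins the outputs of every analysis stage for one transcription factor
#' into a single wide row: coverage and similarity coefficients, size ratio
#' and recall in both directions, the nine contingency ratios, both
#' conditional-given-high distributions, and (optionally) HOT fractions.
#'
#' @param tf TF name.
#' @param metrics One-row tibble from [overlap_metrics()].
#' @param contingency A `bin_contingency` object.
#' @param match_ab,match_ba One-row tibbles from [match_stats()] (A matched
#'   by B, and the converse).
#' @param cond_a_given_bh,cond_b_given_ah `conditional_distribution`
#'   objects.
#' @param hot_a,hot_b Optional HOT-fraction tibbles per database.
#' @return One-row wide tibble; HOT columns are `NA` when no HOT track was
#'   supplied.
#' @export
summarize_tf <- function(tf, metrics, contingency, match_ab, match_ba,
                         cond_a_given_bh, cond_b_given_ah,
                         hot_a = NULL, hot_b = NULL) {
  for (nm in c("metrics", "contingency", "match_ab", "match_ba",
               "cond_a_given_bh", "cond_b_given_ah")) {
    if (is.null(get(nm))) abort(paste0("missing upstream stage: ", nm))
  }
  ratio_cols <- tidy(contingency) |>
    mutate(key = paste0("ratio_", .data$bin_a, .data$bin_b)) |>
    select(all_of(c("key", "ratio"))) |>
    tidyr::pivot_wider(names_from = "key", values_from = "ratio")
  cond_cols <- tibble(
    !!!setNames(as.list(cond_a_given_bh$probs),
                paste0("p_A", bin_levels, "_given_BH")),
    !!!setNames(as.list(cond_b_given_ah$probs),
                paste0("p_B", bin_levels, "_given_AH"))
  )
  hot_frac <- function(h) {
    if (is.null(h)) NA_real_ else h$fraction[h$stratum == "all"]
  }
  hot_matched_frac <- function(h) {
    if (is.null(h) || !"matched" %in% h$stratum) NA_real_
    else h$fraction[h$stratum == "matched"]
  }
  dplyr::bind_cols(
    tibble(tf = tf),
    metrics,
    tibble(
      size_ratio_ab = match_ab$size_ratio,
      recall_a_by_b = match_ab$recall,
      recall_b_by_a = match_ba$recall,
      n_pairs = contingency$total
    ),
    ratio_cols,
    cond_cols,
    tibble(
      hot_fraction_a = hot_frac(hot_a),
      hot_fraction_b = hot_frac(hot_b),
      hot_fraction_matched_a = hot_matched_frac(hot_a),
      hot_fraction_matched_b = hot_matched_frac(hot_b)
    )
  )
}
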