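#' Run the full two-database concordance comparison
#'
#' Orchestrates, for every eligible transcription factor, the whole
#' analysis: pooled signal-outlier filtering, summit windowing and merging
#' per database, base-pair overlap coefficients, signal-bin assignment and
#' the genometric join, the 3x3 bin contingency against the independence
#' null, left-outer matches in both directions, conditional distributions
#' given a high-signal match, and (if a HOT track is supplied) HOT overlap
#' fractions. The run is deterministic: identical inputs give identical
#' outputs.
#'
#' @param peaks Stacked tibble of labelled peaks (columns `chrom` ... `peak`
#'   plus `tf`, `cell`, `database`, `sample_id`), e.g. from
#'   [read_peak_manifest()] or [generate_database_pair()]; alternatively the
#'   path to a manifest TSV.
#' @param databases Length-2 character vector naming the A and B databases,
#'   in that order. Defaults to the two databases present (sorted).
#' @param cell Optional cell-line filter.
#' @param hot Optional HOT/blacklist intervals (tibble or BED path).
#' @param half_window Summit window half-width, bp (default 100).
#' @param outlier_percentile Signal filter percentile (default 90).
#' @param q_low,q_high Bin quantiles (defaults 0.25 / 0.75).
#' @param max_samples Per-TF, per-database sample cap (default 9).
#' @param marginals Contingency null: `"nominal"` or `"empirical"`.
#' @param filter_scope Apply the outlier filter to the `"pooled"` per-TF,
#'   per-database distribution (default) or `"per_sample"`.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSVs (see [write_comparison()]).
#' @return A `peak_comparison` object: list of tibbles `summary` (one row
#'   per TF), `metrics`, `preprocessing`, `contingency` (long),
#'   `conditional` (long), `match`, `hot_fractions`, plus `params` and the
#'   per-TF `details` (pairs, contingency and distribution objects).
#' @export
run_compare <- function(peaks, databases = NULL, cell = NULL, hot = NULL,
                        half_window = 100, outlier_percentile = 90,
                        q_low = 0.25, q_high = 0.75, max_samples = 9,
                        marginals = c("nominal", "empirical"),
                        filter_scope = c("pooled", "per_sample"),
                        out_dir = NULL) {
  marginals <- match.arg(marginals)
  filter_scope <- match.arg(filter_scope)
  if (is.character(peaks) && length(peaks) == 1L) {
    peaks <- read_peak_manifest(peaks)
  }
  stopifnot(is.data.frame(peaks))
  need <- c("chrom", "start", "end", "signalValue", "peak",
            "tf", "cell", "database", "sample_id")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols)) {
    abort(paste0("peaks lack columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(cell)) peaks <- filter(peaks, .data$cell == .env$cell)
  if (nrow(peaks) == 0L) abort("no peaks after filtering")

  dbs <- sort(unique(peaks$database))
  if (is.null(databases)) databases <- dbs
  if (length(databases) != 2L || !all(databases %in% dbs)) {
    abort(paste0(
      "need exactly two databases; present: ", paste(dbs, collapse = ", ")
    ))
  }
  peaks <- filter(peaks, .data$database %in% .env$databases)

  eligible <- select_eligible_tfs(peaks, max_samples = max_samples,
                                  databases = databases)
  if (length(eligible) == 0L) {
    inventory <- peaks |>
      dplyr::distinct(.data$database, .data$tf) |>
      group_by(.data$database) |>
      summarise(tfs = paste(sort(.data$tf), collapse = ","), .groups = "drop")
    abort(paste0(
      "no eligible TFs (present in both databases with <= ", max_samples,
      " samples). Inventory: ",
      paste(inventory$database, inventory$tfs, sep = ": ", collapse = " | ")
    ))
  }

  hot_tbl <- if (is.null(hot)) NULL
    else if (is.character(hot)) read_bed(hot) else merge_bed_intervals(hot)

  per_tf <- purrr::map(eligible, function(one_tf) {
    compare_one_tf(
      filter(peaks, .data$tf == .env$one_tf),
      tf = one_tf, databases = databases, hot = hot_tbl,
      half_window = half_window, outlier_percentile = outlier_percentile,
      q_low = q_low, q_high = q_high, marginals = marginals,
      filter_scope = filter_scope
    )
  })
  names(per_tf) <- eligible

  result <- structure(
    list(
      summary = bind_rows(purrr::map(per_tf, "summary")),
      metrics = bind_rows(purrr::map(per_tf, "metrics")),
      preprocessing = bind_rows(purrr::map(per_tf, "preprocessing")),
      contingency = bind_rows(purrr::map(per_tf, "contingency_long")),
      conditional = bind_rows(purrr::map(per_tf, "conditional_long")),
      match = bind_rows(purrr::map(per_tf, "match")),
      pairs = bind_rows(purrr::map(per_tf, "pairs_long")),
      hot_fractions = bind_rows(purrr::map(per_tf, "hot_long")),
      details = per_tf,
      params = list(
        databases = databases, cell = cell, half_window = half_window,
        outlier_percentile = outlier_percentile, q_low = q_low,
        q_high = q_high, max_samples = max_samples, marginals = marginals,
        filter_scope = filter_scope
      )
    ),
    class = "peak_comparison"
  )
  if (!is.null(out_dir)) write_comparison(result, out_dir)
  result
}

compare_one_tf <- function(tf_peaks, tf, databases, hot, half_window,
                           outlier_percentile, q_low, q_high, marginals,
                           filter_scope) {
  prep <- purrr::map(databases, function(db) {
    db_peaks <- filter(tf_peaks, .data$database == .env$db)
    if (filter_scope == "per_sample") {
      db_peaks <- db_peaks |>
        group_by(.data$sample_id) |>
        dplyr::group_modify(~ filter_signal_outliers(.x, outlier_percentile)) |>
        ungroup()
      pp <- preprocess_peaks(db_peaks, half_window, percentile = NULL)
    } else {
      pp <- preprocess_peaks(db_peaks, half_window, outlier_percentile)
    }
    pp$report <- mutate(pp$report, tf = tf, database = db, .before = 1)
    pp$regions <- assign_signal_bins(pp$regions, q_low, q_high)
    pp
  })
  names(prep) <- c("A", "B")
  reg_a <- prep$A$regions
  reg_b <- prep$B$regions

  metrics <- overlap_metrics(reg_a, reg_b) |>
    mutate(tf = tf, .before = 1)

  pairs <- genometric_join(reg_a, reg_b)
  contingency <- if (nrow(pairs) > 0) bin_contingency(pairs, marginals) else NULL
  match_a <- left_outer_match(reg_a, reg_b)
  match_b <- left_outer_match(reg_b, reg_a)
  stats_a <- match_stats(match_a)
  stats_b <- match_stats(match_b)
  cond_a <- if (nrow(pairs) > 0) conditional_given_high(pairs, side = "B") else NULL
  cond_b <- if (nrow(pairs) > 0) conditional_given_high(pairs, side = "A") else NULL

  hot_a <- hot_b <- NULL
  if (!is.null(hot)) {
    hot_a <- hot_overlap_fraction(match_a, hot)
    hot_b <- hot_overlap_fraction(match_b, hot)
  }

  summary <- if (!is.null(contingency)) {
    summarize_tf(tf, metrics[-1], contingency, stats_a, stats_b,
                 cond_a, cond_b, hot_a, hot_b) |>
      mutate(tf = .env$tf)
  } else {
    mutate(metrics, size_ratio_ab = stats_a$size_ratio,
           recall_a_by_b = stats_a$recall, recall_b_by_a = stats_b$recall,
           n_pairs = 0L)
  }

  list(
    summary = summary,
    metrics = metrics,
    preprocessing = bind_rows(prep$A$report, prep$B$report),
    contingency_long = if (!is.null(contingency)) {
      mutate(tidy(contingency), tf = .env$tf, .before = 1)
    },
    conditional_long = if (!is.null(cond_a)) {
      bind_rows(
        mutate(tidy(cond_a), condition = cond_a$condition, n = cond_a$n),
        mutate(tidy(cond_b), condition = cond_b$condition, n = cond_b$n)
      ) |> mutate(tf = .env$tf, .before = 1)
    },
    match = bind_rows(
      mutate(stats_a, direction = paste(databases[1], "by", databases[2])),
      mutate(stats_b, direction = paste(databases[2], "by", databases[1]))
    ) |> mutate(tf = .env$tf, .before = 1),
    pairs_long = if (nrow(pairs)) mutate(pairs, tf = .env$tf, .before = 1),
    hot_long = if (!is.null(hot_a)) {
      bind_rows(
        mutate(hot_a, database = databases[1]),
        mutate(hot_b, database = databases[2])
      ) |> mutate(tf = .env$tf, .before = 1)
    },
    objects = list(contingency = contingency, cond_a_given_bh = cond_a,
                   cond_b_given_ah = cond_b)
  )
}

#' Write a comparison's result tables as TSVs
#'
#' Emits `summary.tsv`, `metrics.tsv`, `preprocessing.tsv`,
#' `contingency.tsv`, `conditional.tsv`, `match.tsv`, `pairs.tsv` and, when
#' HOT fractions were computed, `hot_fractions.tsv`. Undefined values are
#' written as empty fields (`NA` in R), never as 0. Re-running on identical
#' inputs overwrites byte-identically.
#'
#' @param comparison A `peak_comparison` from [run_compare()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_comparison <- function(comparison, out_dir) {
  stopifnot(inherits(comparison, "peak_comparison"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("summary", "metrics", "preprocessing", "contingency",
              "conditional", "match", "pairs", "hot_fractions")
  for (nm in tables) {
    tab <- comparison[[nm]]
    if (!is.null(tab) && nrow(tab) > 0) {
      readr::write_tsv(tab, file.path(out_dir, paste0(nm, ".tsv")),
                       na = "", progress = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("Peak-database comparison:", paste(x$params$databases, collapse = " vs "),
      "\n", nrow(x$summary), "TF(s):",
      paste(head(x$summary$tf, 10), collapse = ", "), "\n\n")
  cols <- intersect(
    c("tf", "jaccard_general", "alroy_forbes", "size_ratio_ab",
      "recall_a_by_b", "ratio_HH"),
    names(x$summary)
  )
  print(x$summary[cols])
  invisible(x)
}

#' @describeIn run_compare One row per TF and contingency cell (the long
#'   contingency table joined with the per-TF coefficients).
#' @param x A `peak_comparison` object.
#' @param ... Unused.
#' @export
tidy.peak_comparison <- function(x, ...) {
  left_join(x$contingency,
            select(x$summary, all_of(c("tf", "jaccard_general", "alroy_forbes"))),
            by = "tf")
}

#' @describeIn run_compare One-row run summary: TF count and
#'   coverage-weighted means of the headline coefficients.
#' @export
glance.peak_comparison <- function(x, ...) {
  tibble(
    n_tf = nrow(x$summary),
    mean_jaccard = mean(x$summary$jaccard_general, na.rm = TRUE),
    mean_forbes = mean(x$summary$alroy_forbes, na.rm = TRUE),
    mean_recall_a = mean(x$summary$recall_a_by_b, na.rm = TRUE),
    mean_ratio_HH = if ("ratio_HH" %in% names(x$summary))
      mean(x$summary$ratio_HH, na.rm = TRUE) else NA_real_
  )
}

#' @describeIn run_compare Faceted heatmap of observed/expected bin ratios,
#'   one panel per TF.
#' @param object A `peak_comparison` object.
#' @export
autoplot.peak_comparison <- function(object, ...) {
  d <- object$contingency
  if (is.null(d) || nrow(d) == 0) abort("no contingency data to plot")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_b, y = .data$bin_a,
                                  fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~tf) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 obs/exp") +
    ggplot2::labs(x = "signal bin, database B", y = "signal bin, database A")
}

#' Benchmark the pipeline against planted synthetic effects
#'
#' Generates a synthetic database pair for every row of a parameter grid,
#' runs the full comparison, and tabulates the recovered statistics — the
#' (H,H) observed/expected ratio, recall of A by B, Jaccard and Forbes —
#' against the planted `signal_dependence` and detection probabilities.
#'
#' @param grid Data frame whose columns override [synthetic_config()]
#'   arguments (e.g. `signal_dependence`, `detect_prob_b`); one run per row.
#'   An empty grid yields an empty report.
#' @param base_config Optional named list of further config overrides shared
#'   by all runs.
#' @param seed Integer; run i uses `seed + i - 1`.
#' @return Tibble: the grid columns plus `n_pairs`, `ratio_HH`,
#'   `recall_a_by_b`, `jaccard_general`, `alroy_forbes`.
#' @export
run_benchmark <- function(grid, base_config = list(), seed = 1L) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) {
    return(tibble(n_pairs = integer(), ratio_HH = double(),
                  recall_a_by_b = double(), jaccard_general = double(),
                  alroy_forbes = double()))
  }
  purrr::map(seq_len(nrow(grid)), function(i) {
    args <- c(as.list(grid[i, , drop = FALSE]), base_config)
    args$seed <- as.integer(seed) + i - 1L
    cfg <- do.call(synthetic_config, args)
    pair <- generate_database_pair(cfg)
    cmp <- run_compare(bind_rows(pair$peaks_a, pair$peaks_b))
    s <- cmp$summary
    dplyr::bind_cols(
      as_tibble(grid[i, , drop = FALSE]),
      tibble(
        n_pairs = s$n_pairs,
        ratio_HH = if ("ratio_HH" %in% names(s)) s$ratio_HH else NA_real_,
        recall_a_by_b = s$recall_a_by_b,
        jaccard_general = s$jaccard_general,
        alroy_forbes = s$alroy_forbes
      )
    )
  }) |>
    bind_rows()
}
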