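mk_peaks <- function(signal, start = NULL, width = 200L, peak = width %/% 2L,
                     chrom = "chr1") {
  n <- length(signal)
  if (is.null(start)) start <- seq(0L, by = 1000L, length.out = n)
  tibble::tibble(
    chrom = chrom, start = start, end = start + width,
    name = sprintf("p%d", seq_len(n)), score = 0L, strand = ".",
    signalValue = signal, pValue = -1, qValue = -1,
    peak = rep(peak, length.out = n)
  )
}

test_that("signal filter drops values above the interpolated percentile", {
  x <- mk_peaks(1:10)
  kept <- filter_signal_outliers(x, 90)
  # p90 of 1..10 by linear interpolation is 9.1: only the 10 goes
  expect_equal(nrow(kept), 9L)
  expect_equal(kept$signalValue, 1:9)

  # oracle: sort, interpolate, drop strictly greater
  set.seed(4)
  v <- round(stats::rlnorm(57, 2, 1), 3)
  o <- sort(v)
  h <- (length(o) - 1) * 0.9 + 1
  p90 <- o[floor(h)] + (h - floor(h)) * (o[floor(h) + 1] - o[floor(h)])
  expect_equal(
    sort(filter_signal_outliers(mk_peaks(v), 90)$signalValue),
    o[o <= p90]
  )
})

test_that("filter keeps ties, preserves order, validates arguments", {
  x <- mk_peaks(rep(7, 12))
  expect_equal(nrow(filter_signal_outliers(x)), 12L)

  y <- mk_peaks(c(5, 1, 9, 3, 7))
  expect_equal(filter_signal_outliers(y, 60)$signalValue, c(5, 1, 3))

  expect_error(filter_signal_outliers(x, 0), "percentile")
  expect_error(filter_signal_outliers(x, 100), "percentile")
  expect_equal(nrow(filter_signal_outliers(x[0, ], 90)), 0L)
})

test_that("summit windows span half_window on each side of the summit", {
  x <- mk_peaks(20, start = 100L, peak = 50L)  # summit at 150
  r <- summit_windows(x, 100)
  expect_equal(r$start, 50L)
  expect_equal(r$end, 251L)
  expect_equal(r$end - r$start, 201L)
  expect_equal(r$summit, 150L)
  expect_equal(r$n_merged, 1L)

  # clipped at the chromosome origin
  x2 <- mk_peaks(5, start = 0L, peak = 30L)  # summit 30
  r2 <- summit_windows(x2, 100)
  expect_equal(r2$start, 0L)
  expect_equal(r2$end, 131L)

  # degenerate half_window
  r3 <- summit_windows(x, 0)
  expect_equal(r3$end - r3$start, 1L)
  expect_equal(r3$start, 150L)
})

test_that("summit-less records are skipped with a warning and counted", {
  x <- mk_peaks(c(1, 2))
  x$peak[2] <- -1L
  expect_warning(r <- summit_windows(x), "without a summit")
  expect_equal(nrow(r), 1L)
  expect_equal(attr(r, "n_missing_summit"), 1L)
})

test_that("overlapping windows merge to union span with mean signal and summit", {
  # two 201 bp windows, signals 20 and 8, overlapping
  x <- mk_peaks(c(20, 8), start = c(0L, 120L), width = 240L, peak = c(120L, 80L))
  r <- merge_overlapping_windows(summit_windows(x))
  expect_equal(nrow(r), 1L)
  expect_equal(r$signalValue, 14)
  expect_equal(r$summit, as.integer(mean(c(120, 200))))
  expect_equal(r$start, 20L)   # union of [20,221) and [100,301)
  expect_equal(r$end, 301L)
  expect_equal(r$n_merged, 2L)
})

test_that("disjoint windows pass through unchanged", {
  x <- mk_peaks(c(3, 4), start = c(0L, 5000L))
  w <- summit_windows(x)
  r <- merge_overlapping_windows(w)
  expect_equal(nrow(r), 2L)
  expect_equal(r$signalValue, w$signalValue)
  expect_equal(r$start, w$start)
})

test_that("merging is transitive over chains", {
  # A overlaps B, B overlaps C, A and C disjoint
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 150L, 300L), end = c(201L, 351L, 501L),
    signalValue = c(6, 12, 18), summit = c(100L, 250L, 400L), n_merged = 1L
  )
  r <- merge_overlapping_windows(w)
  expect_equal(nrow(r), 1L)
  expect_equal(r$signalValue, 12)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 501L)
  expect_equal(r$n_merged, 3L)
})

test_that("bookended windows (half-open adjacency) are not merged", {
  w <- tibble::tibble(
    chrom = "chr1", start = c(0L, 201L), end = c(201L, 402L),
    signalValue = c(1, 2), summit = c(100L, 301L), n_merged = 1L
  )
  expect_equal(nrow(merge_overlapping_windows(w)), 2L)
})

test_that("merge agrees with the brute-force component oracle and its invariants", {
  set.seed(101)
  for (rep in 1:25) {
    w <- random_windows(sample(2:200, 1))
    got <- merge_overlapping_windows(w)
    want <- brute_merge(w)
    expect_equal(as.data.frame(got[names(want)]), as.data.frame(want))

    # outputs pairwise non-overlapping
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
    # coverage preserved
    expect_equal(sweep_coverage(got), sweep_coverage(w))
    # mean signal within input range per component; summit inside region
    expect_true(all(got$signalValue >= min(w$signalValue) - 1e-12))
    expect_true(all(got$signalValue <= max(w$signalValue) + 1e-12))
    expect_true(all(got$start <= got$summit & got$summit < got$end))

    # permutation invariance
    perm <- w[sample(nrow(w)), ]
    expect_equal(merge_overlapping_windows(perm), got)
  }
})

test_that("TF eligibility needs both databases and the sample cap", {
  samples <- tibble::tibble(
    tf = c(rep("CTCF", 3), rep("ONLYA", 2), rep("MANY", 21)),
    database = c("A", "A", "B", "A", "A", rep(c("A", "B"), c(10, 11))),
    sample_id = c("s1", "s2", "s1", "s1", "s2",
                  paste0("s", 1:10), paste0("s", 1:11))
  )
  expect_equal(select_eligible_tfs(samples), "CTCF")
  # raising the cap admits the heavily sampled TF, sorted order
  expect_equal(select_eligible_tfs(samples, max_samples = 11), c("CTCF", "MANY"))
  expect_equal(select_eligible_tfs(samples[0, ]), character())
})

test_that("preprocess_peaks composes the stages and reports counts", {
  x <- mk_peaks(c(20, 8, 100), start = c(0L, 120L, 5000L),
                width = 240L, peak = c(120L, 80L, 120L))
  pp <- preprocess_peaks(x, percentile = 60)
  expect_equal(pp$report$n_input, 3L)
  expect_equal(pp$report$n_filtered_outlier, 1L)  # the 100 exceeds p60
  expect_equal(pp$report$n_regions_out, 1L)
  expect_equal(pp$regions$signalValue, 14)
})
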