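reg2 <- function(start, end, signal = NULL, chrom = "chr1") {
  x <- tibble::tibble(chrom = chrom, start = as.integer(start),
                      end = as.integer(end))
  if (!is.null(signal)) x$signalValue <- signal
  x
}

binned <- function(start, end, bin, signal = seq_along(start), chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    signalValue = signal,
    bin = factor(bin, levels = c("L", "M", "H"), ordered = TRUE)
  )
}

test_that("rank binning yields the 1:2:1 design on a smooth distribution", {
  r <- assign_signal_bins(reg2(seq(0, 990, 10), seq(5, 995, 10), signal = 1:100))
  expect_equal(as.vector(table(r$bin)), c(25, 50, 25))
  # oracle: rank sort + interpolated quantile thresholds
  q <- stats::quantile(1:100, c(.25, .75), names = FALSE)
  expect_equal(r$bin == "L", r$signalValue <= q[1])
  expect_equal(r$bin == "H", r$signalValue > q[2])
})

test_that("binning degenerates predictably on ties and tiny inputs", {
  r <- suppressWarnings(
    assign_signal_bins(reg2(c(0, 10, 20), c(5, 15, 25), signal = c(7, 7, 7)))
  )
  expect_true(all(r$bin == "L"))
  expect_warning(
    one <- assign_signal_bins(reg2(0, 5, signal = 3)),
    "unstable"
  )
  expect_equal(as.character(one$bin), "L")
  expect_error(assign_signal_bins(reg2(0, 5, signal = 1), q_low = 0.8,
                                  q_high = 0.2), "q_low")
  empty <- assign_signal_bins(reg2(integer(), integer(), signal = double()))
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty$bin, "factor")
})

test_that("overlap join pairs regions sharing at least one base", {
  # single shared base
  p <- genometric_join(reg2(0, 100), reg2(99, 200))
  expect_equal(nrow(p), 1L)
  expect_equal(p$overlap_bp, 1L)
  # half-open adjacency is not overlap
  expect_equal(nrow(genometric_join(reg2(0, 100), reg2(100, 200))), 0L)
  # many-to-many: one A region, two B partners
  p2 <- genometric_join(reg2(0, 300), reg2(c(50, 200), c(150, 250)))
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$overlap_bp, c(100L, 50L))
})

test_that("join carries both bin labels onto each matched pair", {
  a <- binned(0, 100, "H")
  b <- binned(c(50, 99), c(98, 200), c("L", "M"))
  p <- genometric_join(a, b)
  expect_equal(as.character(p$bin_a), c("H", "H"))
  expect_equal(as.character(p$bin_b), c("L", "M"))
})

test_that("join equals the brute-force all-pairs oracle on random sets", {
  set.seed(23)
  for (i in 1:20) {
    A <- random_disjoint(sample(2:80, 1))
    B <- random_disjoint(sample(2:80, 1))
    got <- genometric_join(A, B)[, c("chrom", "start_a", "end_a",
                                     "start_b", "end_b", "overlap_bp")]
    want <- brute_join(A, B)
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})

test_that("left outer match flags A regions confirmed by B", {
  A <- reg2(c(0, 500, 1000), c(100, 600, 1100))
  B <- reg2(c(50, 2000), c(70, 2100))
  m <- left_outer_match(A, B)
  expect_equal(m$matched, c(TRUE, FALSE, FALSE))
  s <- match_stats(m)
  expect_equal(s$recall, 1 / 3)
  expect_equal(s$size_ratio, 3 / 2)
  expect_equal(s$n_matched, 1L)

  # B covering A positionally -> recall 1; disjoint -> recall 0
  expect_equal(match_stats(left_outer_match(A, reg2(0, 1200)))$recall, 1)
  expect_equal(match_stats(left_outer_match(A, reg2(5000, 5100)))$recall, 0)
  expect_error(left_outer_match(A, reg2(integer(), integer())), "empty")
})

test_that("recall equals the fraction of A regions appearing in >= 1 pair", {
  set.seed(31)
  for (i in 1:10) {
    A <- random_disjoint(sample(5:60, 1))
    B <- random_disjoint(sample(5:60, 1))
    m <- left_outer_match(A, B)
    pairs <- genometric_join(A, B)
    n_in_pairs <- nrow(dplyr::distinct(pairs, start_a, end_a))
    expect_equal(match_stats(m)$recall, n_in_pairs / nrow(A))
  }
})

test_that("nominal contingency expectations are the 1:2:1 outer product", {
  pairs <- tibble::tibble(
    chrom = "chr1", start_a = 1:8, end_a = 2:9, start_b = 1:8, end_b = 2:9,
    bin_a = factor(c("H", "H", "L", "M", "M", "M", "H", "L"), c("L", "M", "H")),
    bin_b = factor(c("H", "M", "L", "M", "H", "M", "H", "L"), c("L", "M", "H"))
  )
  ct <- bin_contingency(pairs)
  expect_equal(ct$expected["H", "H"], 0.0625)
  expect_equal(rowSums(ct$expected), c(L = 0.25, M = 0.5, H = 0.25))
  expect_equal(sum(ct$expected), 1)
  expect_equal(sum(ct$observed), 1)
  expect_equal(ct$total, 8L)
  # observed (H,H) = 2/8 = 0.25 -> ratio 4 under the nominal null
  expect_equal(ct$ratio["H", "H"], 0.25 / 0.0625)
  # a cell observed at 0.125 would have ratio exactly 2 (0.125 / 0.0625)
  expect_equal(ct$observed["L", "L"] / ct$expected["L", "L"], 4)

  td <- tidy(ct)
  expect_equal(sum(td$count), 8L)
  expect_equal(td$ratio[td$bin_a == "H" & td$bin_b == "H"], 4)
  g <- glance(ct)
  expect_equal(g$ratio_HH, 4)
  expect_error(bin_contingency(pairs[0, ]), "no matched pairs")
})

test_that("independently drawn bins give ratios near 1 (3 SE) at n = 1e4", {
  set.seed(97)
  n <- 1e4
  pairs <- tibble::tibble(
    chrom = "chr1", start_a = 1:n, end_a = 2:(n + 1),
    start_b = 1:n, end_b = 2:(n + 1),
    bin_a = factor(sample(c("L", "M", "H"), n, TRUE, c(.25, .5, .25)),
                   c("L", "M", "H")),
    bin_b = factor(sample(c("L", "M", "H"), n, TRUE, c(.25, .5, .25)),
                   c("L", "M", "H"))
  )
  ct <- bin_contingency(pairs)
  se <- sqrt(ct$expected * (1 - ct$expected) / n) / ct$expected
  expect_true(all(abs(ct$ratio - 1) <= 3 * se))
})

test_that("empirical marginals absorb a distorted bin design", {
  set.seed(5)
  n <- 4000
  # bins heavily tied: 60% L, 30% M, 10% H on both sides, independent
  pairs <- tibble::tibble(
    chrom = "chr1", start_a = 1:n, end_a = 2:(n + 1),
    start_b = 1:n, end_b = 2:(n + 1),
    bin_a = factor(sample(c("L", "M", "H"), n, TRUE, c(.6, .3, .1)),
                   c("L", "M", "H")),
    bin_b = factor(sample(c("L", "M", "H"), n, TRUE, c(.6, .3, .1)),
                   c("L", "M", "H"))
  )
  emp <- bin_contingency(pairs, marginals = "empirical")
  expect_equal(sum(emp$expected), 1)
  expect_true(all(abs(emp$ratio - 1) < 0.35))
  # the nominal null is strongly violated by construction
  nom <- bin_contingency(pairs, marginals = "nominal")
  expect_gt(nom$ratio["L", "L"], 3)
})

test_that("region-level counting deduplicates multi-partner pairs", {
  pairs <- genometric_join(
    binned(0, 300, "H"),
    binned(c(50, 200), c(150, 250), c("M", "M"))
  )
  expect_equal(bin_contingency(pairs)$total, 2L)
  expect_equal(bin_contingency(pairs, level = "regions")$total, 1L)
})
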