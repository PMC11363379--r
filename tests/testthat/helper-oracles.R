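# Independent brute-force oracles, deliberately naive: per-base membership
# sweeps and all-pairs loops in base R, no interval library. Only usable on
# small coordinate spaces.

# Per-base coverage sweep: a/b/c counts over one implicit chromosome set.
sweep_counts <- function(set_a, set_b) {
  chroms <- union(unique(set_a$chrom), unique(set_b$chrom))
  acc <- c(a = 0, b = 0, c = 0)
  for (ch in chroms) {
    ga <- set_a[set_a$chrom == ch, , drop = FALSE]
    gb <- set_b[set_b$chrom == ch, , drop = FALSE]
    top <- max(c(ga$end, gb$end, 0L))
    in_a <- rep(FALSE, top)
    in_b <- rep(FALSE, top)
    for (i in seq_len(nrow(ga))) in_a[(ga$start[i] + 1):ga$end[i]] <- TRUE
    for (i in seq_len(nrow(gb))) in_b[(gb$start[i] + 1):gb$end[i]] <- TRUE
    acc["a"] <- acc["a"] + sum(in_a & in_b)
    acc["b"] <- acc["b"] + sum(in_a & !in_b)
    acc["c"] <- acc["c"] + sum(!in_a & in_b)
  }
  tibble::tibble(a = acc[["a"]], b = acc[["b"]], c = acc[["c"]],
                 n = sum(acc))
}

# Per-base coverage of one region set (for conditional denominators etc.).
sweep_coverage <- function(x) {
  cov <- 0L
  for (ch in unique(x$chrom)) {
    g <- x[x$chrom == ch, , drop = FALSE]
    in_x <- rep(FALSE, max(g$end))
    for (i in seq_len(nrow(g))) in_x[(g$start[i] + 1):g$end[i]] <- TRUE
    cov <- cov + sum(in_x)
  }
  cov
}

overlaps_bp <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# Connected components of the all-pairs overlap graph (breadth-first search
# over the boolean adjacency matrix), then one-shot means per component.
brute_merge <- function(regions) {
  out <- list()
  for (ch in unique(regions$chrom)) {
    g <- regions[regions$chrom == ch, , drop = FALSE]
    n <- nrow(g)
    adj <- outer(g$start, g$end, `<`) & outer(g$end, g$start, `>`)
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      k <- k + 1L
      frontier <- i
      while (length(frontier)) {
        comp[frontier] <- k
        nxt <- which(is.na(comp) & colSums(adj[frontier, , drop = FALSE]) > 0)
        frontier <- nxt
      }
    }
    for (kk in seq_len(k)) {
      m <- g[comp == kk, , drop = FALSE]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch,
        start = min(m$start), end = max(m$end),
        signalValue = mean(m$signalValue),
        summit = as.integer(floor(mean(m$summit))),
        n_merged = nrow(m)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$start), ]
}

# All-pairs overlap join (row-vectorized over set_b).
brute_join <- function(set_a, set_b) {
  out <- list()
  for (i in seq_len(nrow(set_a))) {
    same <- set_b$chrom == set_a$chrom[i]
    ov <- pmin(set_a$end[i], set_b$end) - pmax(set_a$start[i], set_b$start)
    hit <- same & ov > 0
    if (any(hit)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = set_a$chrom[i],
        start_a = set_a$start[i], end_a = set_a$end[i],
        start_b = set_b$start[hit], end_b = set_b$end[hit],
        overlap_bp = as.integer(ov[hit])
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res[order(res$chrom, res$start_a, res$start_b), ] else res
}

# Random possibly-overlapping summit windows on a small coordinate space.
random_windows <- function(n, max_coord = 1e4, chrom = "chrT") {
  summit <- sample.int(max_coord, n, replace = TRUE)
  half <- sample(5:60, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom,
    start = pmax(summit - half, 0L),
    end = summit + half + 1L,
    signalValue = round(stats::runif(n, 0.5, 50), 3),
    summit = as.integer(summit),
    n_merged = 1L
  )
}

# Random internally non-overlapping region set (oracle-made: brute merge of
# random windows, stripped of merge metadata).
random_disjoint <- function(n, max_coord = 1e4, chrom = "chrT") {
  m <- brute_merge(random_windows(n, max_coord, chrom))
  m$n_merged <- 1L
  m
}
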