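#' Configuration for the paired-database peak simulator
#'
#' Describes a single synthetic chromosome ("chrS") carrying latent true
#' binding sites that two pseudo-databases, A and B, each detect with noise.
#' Defaults emulate one moderately assayed transcription factor: a few
#' thousand well-separated sites with right-skewed (log-normal) strengths,
#' imperfect and summit-jittered detection, database-specific noise peaks
#' with scaled-down signals, and an optional coupling between a site's
#' strength rank and its detection probability (`signal_dependence = 0`
#' reproduces the independence null exactly).
#'
#' @param genome_length Chromosome length in bp.
#' @param n_true_sites Number of latent binding sites.
#' @param detect_prob_a,detect_prob_b Mean detection probability per
#'   database.
#' @param signal_dependence Cross-database consistency knob (>= 0). It
#'   controls both how strongly a site's latent strength raises its
#'   detection probability (logistic in the strength rank) and how strongly
#'   that strength is expressed in each database's reported signalValue
#'   (shared fraction `d/(1+d)` of the log-signal spread). At 0 the two
#'   databases behave as independent random peak callers: detection and
#'   reported signals carry no information about each other, so matched
#'   pairs satisfy the bin-independence null exactly. Larger values make
#'   high-signal sites both easier to detect and consistently high-signal
#'   in the two databases.
#' @param summit_jitter_sd SD (bp) of Gaussian jitter of reported summits
#'   around the true site.
#' @param n_noise_a,n_noise_b Database-specific false peaks.
#' @param signal_lognormal_mu,signal_lognormal_sigma Log-scale mean/SD of
#'   latent site strength.
#' @param signal_noise_sd SD of the multiplicative log-normal measurement
#'   noise applied to reported signalValues.
#' @param noise_signal_scale Multiplier (< 1) applied to noise-peak signals.
#' @param peak_halfwidth_range Integer range (bp) of raw peak half-widths.
#' @param tf,cell Labels stamped on the generated records.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(genome_length = 5e7,
                             n_true_sites = 5000,
                             detect_prob_a = 0.5,
                             detect_prob_b = 0.5,
                             signal_dependence = 1,
                             summit_jitter_sd = 20,
                             n_noise_a = 1000,
                             n_noise_b = 1000,
                             signal_lognormal_mu = log(10),
                             signal_lognormal_sigma = 0.8,
                             signal_noise_sd = 0.25,
                             noise_signal_scale = 0.5,
                             peak_halfwidth_range = c(75L, 300L),
                             tf = "SYNTF1",
                             cell = "synthCell",
                             seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_true_sites = as.integer(n_true_sites),
    detect_prob_a = detect_prob_a, detect_prob_b = detect_prob_b,
    signal_dependence = signal_dependence,
    summit_jitter_sd = summit_jitter_sd,
    n_noise_a = as.integer(n_noise_a), n_noise_b = as.integer(n_noise_b),
    signal_lognormal_mu = signal_lognormal_mu,
    signal_lognormal_sigma = signal_lognormal_sigma,
    signal_noise_sd = signal_noise_sd,
    noise_signal_scale = noise_signal_scale,
    peak_halfwidth_range = as.integer(peak_halfwidth_range),
    tf = tf, cell = cell,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      genome_length > 0, n_true_sites >= 0,
      detect_prob_a >= 0, detect_prob_a <= 1,
      detect_prob_b >= 0, detect_prob_b <= 1,
      signal_dependence >= 0, summit_jitter_sd >= 0,
      n_noise_a >= 0, n_noise_b >= 0,
      signal_lognormal_sigma > 0, signal_noise_sd >= 0,
      noise_signal_scale > 0,
      length(peak_halfwidth_range) == 2L,
      peak_halfwidth_range[1] >= 1L,
      peak_halfwidth_range[1] <= peak_halfwidth_range[2]
    )
  })
  if (cfg$genome_length <= 2 * max(cfg$peak_halfwidth_range)) {
    abort("genome_length must exceed twice the maximum peak width")
  }
  structure(cfg, class = "synthetic_config")
}

# Uniform placement of n points with a guaranteed minimum separation:
# draw order statistics on the free length, then re-insert the gaps.
place_spaced <- function(n, genome_length, min_sep, margin) {
  if (n == 0L) return(integer())
  usable <- genome_length - 2 * margin
  free <- usable - (n - 1) * min_sep
  if (free <= 0) {
    abort(paste0("cannot place ", n, " sites ", min_sep,
                 " bp apart on a ", genome_length, " bp genome"))
  }
  offsets <- sort(runif(n, 0, free))
  as.integer(floor(margin + offsets + min_sep * (seq_len(n) - 1)))
}

# P(detect site i) = base * logistic(dep * (2 r_i - 1)) / mean(logistic(...)),
# where r_i is the centered strength rank in (0, 1). Renormalizing by the
# mean keeps the average detection probability at `base` for every dep, and
# dep = 0 gives a flat logistic(0) so detection is exactly independent of
# strength. Probabilities are capped at 1 (relevant for large base * dep).
detection_probs <- function(strength, base, dep) {
  n <- length(strength)
  if (n == 0L) return(numeric())
  r <- (rank(strength, ties.method = "average") - 0.5) / n
  w <- plogis(dep * (2 * r - 1))
  pmin(base * w / mean(w), 1)
}

#' Generate a matched pair of synthetic peak databases
#'
#' Places latent true sites uniformly (non-overlapping by construction) with
#' log-normal strengths, lets each database detect sites independently, and
#' emits raw narrowPeak-style records: jittered summit centred in a random
#' extent, a right-skewed signalValue, plus uniformly placed noise peaks
#' with scaled-down signals. The returned truth table maps every record to
#' its latent site (`NA` for noise), so planted effects are recoverable.
#'
#' `signal_dependence` sets how much of a site's latent strength shows
#' through: with weight `w = d / (1 + d)` the log-signal reported by
#' database `x` for site `i` is
#' `mu + sigma * (w * z_i + sqrt(1 - w^2) * e_ix)` (plus multiplicative
#' measurement noise), where `z_i` is the site's standardized log-strength
#' and `e_ix` is database-specific; detection probability is
#' logistic-tilted by `d` in the strength rank (see [synthetic_config()]).
#' At `d = 0` detection is flat and the two databases' signals are
#' independent draws, so the signal bins of matched pairs are independent —
#' the exact null of the contingency analysis. Note that scaled-down noise
#' peaks also violate that null (they are low-signal and rarely matched):
#' a pure independence-null fixture needs `signal_dependence = 0` *and*
#' `n_noise_a = n_noise_b = 0`.
#'
#' @param config A [synthetic_config()].
#' @return List with `peaks_a`, `peaks_b` (labelled peak tibbles ready for
#'   [preprocess_peaks()] or [run_compare()]), `truth` (record_id, database,
#'   site_id, strength), and `sites` (site_id, position, strength,
#'   detected_a/b).
#' @export
generate_database_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  hw_max <- max(config$peak_halfwidth_range)
  min_sep <- 2L * hw_max + as.integer(ceiling(4 * config$summit_jitter_sd)) + 2L
  pos <- place_spaced(config$n_true_sites, config$genome_length, min_sep,
                      margin = hw_max + 1L)
  z <- rnorm(config$n_true_sites)
  strength <- exp(config$signal_lognormal_mu + config$signal_lognormal_sigma * z)
  w <- config$signal_dependence / (1 + config$signal_dependence)

  sites <- tibble(
    site_id = seq_len(config$n_true_sites),
    position = pos,
    strength = strength,
    detected_a = runif(config$n_true_sites) <
      detection_probs(strength, config$detect_prob_a, config$signal_dependence),
    detected_b = runif(config$n_true_sites) <
      detection_probs(strength, config$detect_prob_b, config$signal_dependence)
  )

  emit <- function(db_label, detected, n_noise) {
    det <- sites[detected, , drop = FALSE]
    n_det <- nrow(det)
    summit <- det$position +
      as.integer(round(rnorm(n_det, 0, config$summit_jitter_sd)))
    hws <- seq(config$peak_halfwidth_range[1], config$peak_halfwidth_range[2])
    hw <- if (length(hws) == 1L) rep(hws, n_det + n_noise)
      else sample(hws, n_det + n_noise, replace = TRUE)
    # shared strength component (weight w) + database-specific component,
    # then multiplicative measurement noise
    log_sig <- config$signal_lognormal_mu + config$signal_lognormal_sigma *
      (w * z[det$site_id] + sqrt(1 - w^2) * rnorm(n_det))
    sig_true <- exp(log_sig) * exp(rnorm(n_det, 0, config$signal_noise_sd))
    noise_summit <- if (n_noise > 0) {
      as.integer(floor(runif(n_noise, hw_max + 1,
                             config$genome_length - hw_max - 1)))
    } else integer()
    sig_noise <- config$noise_signal_scale *
      rlnorm(n_noise, config$signal_lognormal_mu, config$signal_lognormal_sigma)

    all_summit <- c(summit, noise_summit)
    all_summit <- pmax(all_summit, hw)  # keep extents on the chromosome
    all_sig <- c(sig_true, sig_noise)
    ids <- c(sprintf("%s_det_%05d", db_label, seq_len(n_det)),
             if (n_noise > 0) sprintf("%s_noise_%05d", db_label, seq_len(n_noise)))
    peaks <- tibble(
      chrom = "chrS",
      start = all_summit - hw,
      end = all_summit + hw + 1L,
      name = ids,
      score = 0L,
      strand = ".",
      signalValue = all_sig,
      pValue = -1, qValue = -1,
      peak = hw,  # summit at the centre of the extent
      has_summit = TRUE,
      tf = config$tf, cell = config$cell, database = db_label,
      sample_id = paste0(db_label, "_s1")
    )
    truth <- tibble(
      record_id = ids,
      database = db_label,
      site_id = c(det$site_id, rep(NA_integer_, n_noise)),
      strength = c(det$strength, rep(NA_real_, n_noise))
    )
    list(peaks = peaks, truth = truth)
  }

  a <- emit("A", sites$detected_a, config$n_noise_a)
  b <- emit("B", sites$detected_b, config$n_noise_b)
  list(
    peaks_a = a$peaks,
    peaks_b = b$peaks,
    truth = bind_rows(a$truth, b$truth),
    sites = sites
  )
}

#' Generate non-overlapping synthetic HOT regions
#'
#' Places `n_hot` mutually disjoint intervals of random width uniformly on
#' the synthetic chromosome; deterministic under `seed`.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_hot Number of HOT intervals.
#' @param width_range Integer range of interval widths (bp).
#' @param seed Integer seed.
#' @param chrom Chromosome name (default "chrS").
#' @return Tibble `chrom`, `start`, `end`, internally non-overlapping.
#' @export
generate_hot_regions <- function(genome_length, n_hot,
                                 width_range = c(1000L, 5000L),
                                 seed = 1L, chrom = "chrS") {
  stopifnot(genome_length > 0, n_hot >= 0,
            length(width_range) == 2L, width_range[1] >= 1L,
            width_range[1] <= width_range[2])
  if (n_hot == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (as.numeric(n_hot) * width_range[2] > genome_length) {
    abort("cannot place HOT regions: total width exceeds genome length")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  centers <- place_spaced(n_hot, genome_length,
                          min_sep = width_range[2] + 1L,
                          margin = width_range[2])
  hw <- sample(seq(width_range[1], width_range[2]), n_hot, replace = TRUE)
  tibble(
    chrom = chrom,
    start = pmax(centers - hw %/% 2L, 0L),
    end = centers - hw %/% 2L + hw
  )
}

#' Write a synthetic fixture to disk in the manifest layout
#'
#' Materializes a generated database pair as two narrowPeak files, a
#' manifest TSV the pipeline consumes, and a truth TSV.
#'
#' @param pair Output of [generate_database_pair()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file.
#' @export
write_synthetic_fixture <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "A.narrowPeak")
  fb <- file.path(dir, "B.narrowPeak")
  write_narrowpeak_raw(pair$peaks_a, fa)
  write_narrowpeak_raw(pair$peaks_b, fb)
  man <- tibble(
    path = c("A.narrowPeak", "B.narrowPeak"),
    database = c(pair$peaks_a$database[1], pair$peaks_b$database[1]),
    cell = c(pair$peaks_a$cell[1], pair$peaks_b$cell[1]),
    tf = c(pair$peaks_a$tf[1], pair$peaks_b$tf[1]),
    sample_id = c(pair$peaks_a$sample_id[1], pair$peaks_b$sample_id[1])
  )
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, manifest, progress = FALSE)
  readr::write_tsv(pair$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  manifest
}

# Raw 10-column writer for peak tibbles that already carry narrowPeak columns.
write_narrowpeak_raw <- function(peaks, path) {
  lines <- paste(
    peaks$chrom, as.integer(peaks$start), as.integer(peaks$end), peaks$name,
    as.integer(peaks$score), peaks$strand, sprintf("%.4f", peaks$signalValue),
    peaks$pValue, peaks$qValue, as.integer(peaks$peak),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
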