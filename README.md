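# peakconcord

Signal-stratified concordance analysis of two ChIP-seq peak databases.

Repositories of transcription factor binding sites (ENCODE-style and
Cistrome-style collections, for instance) call peaks from the same
experiments with different pipelines, and their BED narrowPeak sets for the
same factor in the same cell line often disagree in number and position.
`peakconcord` measures that disagreement and asks whether the narrowPeak
`signalValue` — the average enrichment of a peak — predicts where the two
databases agree: are strongly bound sites the consistent ones?

## What it computes

For each transcription factor present in both databases (same cell line,
at most 9 samples per database), the pipeline:

1. removes peaks with `signalValue` above the 90th percentile of the pooled
   per-TF, per-database distribution (right-tail artifacts);
2. shrinks each peak to a 201 bp window around its summit and merges
   overlapping windows across samples into *regions* — union span, mean
   `signalValue`, floored mean summit;
3. accumulates base-pair counts `a` (covered by both sets), `b` (A only),
   `c` (B only), `n = a + b + c`, and reports
   - general Jaccard `a / n`,
   - conditional Jaccard `a / (a + b)` and `a / (a + c)`,
   - the Alroy-corrected Forbes coefficient
     `a (n + √n) / [(a + b)(a + c) + a√n + ½bc]`,
     which is robust to set-size imbalance;
4. rank-bins each database's regions by `signalValue` into L/M/H
   (bottom 25% / middle 50% / top 25%), joins the two sets by ≥1 bp overlap,
   and compares the joint (bin A, bin B) distribution of matched pairs to
   the independence null `P(X, Y) = P(X)·P(Y)` with marginals
   (0.25, 0.50, 0.25) — e.g. `P(H, H) = 0.0625`;
5. reports left-outer recall in both directions, size ratios, the
   conditional distributions `P(bin_A | bin_B = H)` (and converse), and —
   given a HOT/blacklist BED — the fraction of bound bases falling in HOT
   regions per signal stratum and for matched regions.

A seeded synthetic generator (`generate_database_pair()`) produces paired
pseudo-databases with a single consistency knob, so the whole pipeline is
testable without downloading anything: at `signal_dependence = 0` (and no
noise peaks) matched pairs satisfy the independence null exactly; larger
values plant the high-signal co-occurrence the analysis is built to detect.

## Worked example

```r
library(peakconcord)
library(dplyr)

cfg  <- synthetic_config(n_true_sites = 2000, signal_dependence = 2, seed = 42)
pair <- generate_database_pair(cfg)
cmp  <- run_compare(bind_rows(pair$peaks_a, pair$peaks_b))

cmp
#> Peak-database comparison: A vs B
#>  1 TF(s): SYNTF1
#>
#> # A tibble: 1 × 6
#>   tf     jaccard_general alroy_forbes size_ratio_ab recall_a_by_b ratio_HH
#>   <chr>            <dbl>        <dbl>         <dbl>         <dbl>    <dbl>
#> 1 SYNTF1           0.106        0.262             1         0.221     3.33

cmp$details$SYNTF1$objects$contingency
#> Signal-bin contingency (399 pairs, nominal null)
#>
#> observed/expected ratio:
#>    B
#> A       L     M     H
#>   L 0.241 0.461 0.401
#>   M 0.180 0.932 1.724
#>   H 0.321 1.624 3.328
```

Reading the output: the two pseudo-databases overlap weakly in raw position
(Jaccard 0.106; the Forbes coefficient, 0.262, corrects for size imbalance
but stays low), and only 22% of A's regions are confirmed by B. The
contingency ratios show where the agreement concentrates: matched pairs land
in the (H, H) cell 3.3 times more often than independence predicts, while
every L cell is depleted — high-signal sites are the consistent ones, which
is exactly the planted `signal_dependence = 2` structure. The conditional
distribution given a high-signal match makes the same point:

```r
cmp$details$SYNTF1$objects$cond_a_given_bh
#> Conditional signal-bin distribution given B == H (n = 179)
#>      L      M      H
#> 0.0559 0.4804 0.4637
```

against a null of (0.25, 0.50, 0.25). `tidy()`, `glance()` and `autoplot()`
methods exist for the comparison, contingency and conditional objects;
`run_compare(..., out_dir = "out/")` writes every stage's table as TSV.
Real data enters through `read_peak_manifest()` (a TSV of
path/database/cell/tf/sample_id rows pointing at narrowPeak files) and the
same `run_compare()` call; `inst/cli/peakconcord.R` wraps compare/synth/
benchmark subcommands for shell use.

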