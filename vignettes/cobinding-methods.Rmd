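---
title: "Summit-proximity co-binding analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summit-proximity co-binding analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockbind)
```

## The problem

Two transcription factors that occupy the same enhancers leave a
characteristic footprint in their ChIP-seq data: the summit of a peak
of one factor lies within a nucleosome-scale distance of a summit of
the other far more often than chance placement allows. `clockbind`
quantifies this from peak files alone. The motivating biology is the
interplay of the glucocorticoid receptor with the circadian repressors
REVERBa/REVERBb in mouse liver — co-binding there segregates
glucocorticoid action by time of day — but the machinery is generic to
any pair of cistromes.

## The proximity model

For every query peak the package computes the distance to the nearest
reference summit on the same chromosome. The working model is a
two-component mixture:

* a **co-bound** component, in which the query summit sits at a
  reference summit plus a small displacement; displacements are modeled
  (and simulated) as discretized Laplace with scale `b`, a heavy-tailed
  shape that matches the sharp-center/long-tail look of observed
  summit scatter;
* a **background** component, unrelated to the reference. If reference
  summits fell uniformly at density `rho` per bp, a background query
  summit would still land within `theta` bp of one with probability
  `1 - exp(-2 * theta * rho)` (no summit in a window of `2 * theta`).
  `background_proximal_rate()` exposes this closed form, and
  subtracting it from the observed proximal fraction estimates the
  co-bound mixture weight.

Calling a peak co-bound at `theta` = 120 bp, and summarizing a
cistrome pair by the ratio of proximal to non-proximal events, gives a
statistic that is insensitive to the sizes of the two cistromes: peak
count enters both counts proportionally, which the subsampling
invariance tests verify directly.

Real genomes are not uniform — peaks cluster in accessible chromatin —
so on real data the closed-form background rate is a lower bound and
the estimated co-bound fraction correspondingly an upper bound. The
ratio itself makes no uniformity assumption.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `proximal_threshold` | 120 | bp | nucleosome-scale separation distinguishing shared-enhancer binding from unrelated peaks; a distance of exactly 120 counts as non-proximal (strict `<` is proximal, the conservative reading of a "< threshold" rule that leaves the boundary unassigned) |
| `fe_stringencies` | 10, 20, 30 | fold enrichment | three stringency tiers for the query cistrome; FE >= 30 is the high-stringency tier. Filtering is inclusive at the cutoff. Only the top tier has a field-established value; the lower two are evenly spaced below it and overridable |
| `histogram_bin`, `histogram_max` | 20, 3000 | bp | display resolution of the distance histogram; counts beyond the right edge go to an overflow tally so totals are conserved |
| `flank` (metagene) | 2000 | bp | symmetric window around the TSS, i.e. 40 coverage bins |
| `baseline_bp` | 1000 | bp | the stretch immediately preceding the window whose mean count normalizes each site |
| `bin_width` | 100 | bp | coverage bin; windows snap to the bin grid at the bin containing the TSS |
| `min_ratio`, `min_coverage` (motifs) | 1.5, 5% | — | reporting cutoffs for the motif table: observed/expected ratio and the observed fraction as a percentage |

## Decisions where the design was open

Several choices are not forced by the method's description; each is a
deliberate package decision, implemented deterministically and, where
reasonable, switchable.

* **Median interpeak distance.** Both `median_proximal_bp` (over
  proximal pairs only) and `median_all_bp` (over all nearest-neighbor
  distances) are reported, because a "median interpeak distance" can
  be read either way. Note the proximal-only median is a truncated
  statistic: under planted Laplace(`b` = 40 bp) offsets its expectation
  is about 25.8 bp, below the untruncated `b ln 2 = 27.7` bp.
* **Orphan query peaks** (no same-chromosome reference summit) are
  excluded from both proximal and non-proximal counts and reported
  separately — silently dropping them would bias the ratio, silently
  counting them as non-proximal would too.
* **Self-comparison.** When query and reference are the same cistrome,
  the reference peak with the *same name* is excluded per query peak;
  a same-position peak under a different name is a genuine zero
  distance.
* **Nearest-TSS gene assignment** defines "close to a co-bound peak":
  the gene whose TSS is nearest to the query summit, ties broken
  toward the lexicographically smaller gene id (deterministic and
  inspectable). A fixed-window alternative can be had by filtering the
  `distance_to_tss` column; it is not the default because TSS-nearest
  assignment is the standard default of peak annotators.
* **Metagene baseline orientation.** "The 1 kb preceding the site" is
  read along the direction of transcription by default (`oriented =
  TRUE`): for minus-strand genes the baseline lies at higher genomic
  coordinates and the profile axis is mirrored, so the x axis always
  runs upstream-to-downstream of the gene. `oriented = FALSE` gives
  the purely genomic alternative; neither is asserted to be the only
  defensible reading.
* **Zero-baseline sites** are excluded from the profile and counted
  (`n_zero_baseline`) rather than rescued with a pseudocount, which
  would make the fold-change scale depend on an arbitrary constant.
* **Motif %Ratio** uses per-region frequencies: the fraction of target
  regions with at least one hit over the same fraction in background
  regions. Per-occurrence counting is the other possibility; the
  per-region reading is implemented and flagged here as an assumption.
* **Duplicate motifs** are defined as identical IUPAC consensus
  strings (single base at probability >= 0.6, else the degenerate code
  of all bases >= 0.25); among duplicates the higher-%Ratio row
  survives. Any similarity-based alternative would need a threshold
  just as arbitrary and harder to inspect.
* **PWM hit threshold** defaults to 80% of the motif's maximal
  attainable log2-odds score, the common default when per-motif
  calibrated thresholds are unavailable; motif files that carry their
  own threshold keep it. A genomic window hit on both strands (as with
  palindromic motifs) counts once.
* **ddPCR reference sample** is an explicit argument; the default
  (first sample, announced with a message) exists only for
  interactive convenience. The choice rescales all outputs by one
  constant, so between-sample ratios never depend on it.

## The synthetic-data generator

`sim_config()` fixes the study conditions: a toy genome of two 5-Mb
chromosomes, 1000 reference and 2000 query peaks, planted co-bound
fraction 0.3 at Laplace scale 40 bp, lognormal fold enrichment with a
higher location for planted peaks (meanlog `log 40` vs `log 15`, sdlog
0.6) so that high-stringency filtering enriches for true co-binding,
1000 genes, 300-gene DE sets seeded with 60% of the co-bound-proximal
genes (20% of which are shared into the night set so exclusive sets are
nontrivial), and Poisson coverage at rate 5 per 100-bp bin rising to 15
within 500 bp of enriched TSSs (a threefold planted signal). Every
generator is a pure function of `(config, seed)`; stages use offset
seed streams so regenerating one never perturbs another.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: chromatin-driven spatial clustering of
peaks (background proximity on real genomes exceeds the uniform closed
form), mappability and copy-number artifacts beyond a user-supplied
blacklist, fragment-length effects (reads are 5' start positions; no
extension is modeled), replicate structure, and any dependence between
fold enrichment and peak width.

## Numerical and degenerate-input behaviour

* Coordinates are 0-based half-open throughout (BED convention);
  narrowPeak summit offsets of −1 fall back to the interval midpoint,
  `floor((start + end) / 2)`.
* Blacklist filtering removes any item sharing >= 1 bp with a
  blacklist interval; an interval ending exactly where a blacklist
  region starts is kept. The operation is idempotent and commutes with
  blacklist concatenation.
* A distance set with every peak proximal yields ratio `Inf` — a
  reported sentinel, not an error; medians of empty selections are
  `NA`.
* Chromosome names match by exact string equality; fully disjoint name
  sets trigger a warning rather than silent no-ops.
* Metagene windows whose full geometry (window plus baseline) does not
  fit inside the chromosome are dropped, not truncated, so every
  profiled site contributes the same 40 bins.
* Medians use the midpoint of the two central order statistics for
  even counts (R's default).

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: distance-oracle checks up to 500 peaks per side over 100 random
instances; fraction-recovery at 2000 query / 1000 reference peaks over
20 seeds for each planted fraction; median recovery at 5000 planted
pairs; metagene profiles over 200–300 sites on a 10-Mb genome; and
10-fold randomized stratification bookkeeping. These sizes give the
statistics sampling errors comfortably inside the asserted tolerances
while keeping a full run in well under a minute per stage.

## Known limitations

The package deliberately stops short of peak calling, read alignment,
differential-expression fitting, de novo motif discovery, assembly
lift-over, and significance testing of co-binding ratios — the ratio
is a descriptive statistic here, as it is in the analyses it
reproduces. Proximity is summit-to-summit only; a broad peak whose
summit is displaced from a shared enhancer will read as non-proximal
even when the intervals overlap (use `cistrome_overlap()` for an
interval-level view).
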