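---
title: "Methods: bimodal expression fingerprinting for annotation QC"
author: "hlascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimodal expression fingerprinting for annotation QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlascore)
```

## The problem and the model

Clinical transcriptomics studies with several samples per donor depend on
correct donor annotation: a sample silently assigned to the wrong donor
corrupts every downstream supervised analysis. A sex check catches only
cross-sex mix-ups. This package implements a transcript-level fingerprint
that also works within a sex: some microarray probe sets were designed over
polymorphic mRNA sequence, so a donor whose haplotype mismatches the probe
sequence hybridizes poorly and the probe reads out "off", while a matching
haplotype reads "on". Across donors such a probe is **bimodal**; within a
donor it is constant. A small panel of such probes, thresholded to binary
digits, gives each sample a score that must agree across a donor's samples.

Two statistical components follow from this picture:

1. **Discovery** — find bimodal probe sets transcriptome-wide.
2. **Scoring** — reduce samples to digit strings over a fixed panel and
   flag intra-donor disagreements.

## Hartigan's dip statistic

For a sample with empirical CDF $F_n$, the dip is

$$ D(F_n) \;=\; \min_{G \,\in\, \mathcal U} \; \sup_x \lvert F_n(x) - G(x)\rvert, $$

where $\mathcal U$ is the class of unimodal distribution functions (convex
up to a mode, concave after it). `compute_dip()` implements the iterative
greatest-convex-minorant / least-concave-majorant algorithm over candidate
modal intervals. Properties the test suite asserts:

* bounds $1/(2n) \le D \le 1/4$ for $n \ge 2$;
* invariance under strictly increasing affine transforms;
* exact agreement (to $10^{-9}$) with an independent brute-force oracle
  that fits the best unimodal band-constrained CDF for every candidate
  mode position, on hundreds of randomized small samples.

Degenerate inputs are not errors: filtered expression matrices can contain
constant probes, so $n = 1$ and all-tied samples return the lower bound
$1/(2n)$ with a `degenerate` flag. Ties are kept exactly (no jittering);
the algorithm's slope comparisons are cross-multiplied so tied values never
divide by zero.

### Significance by Monte Carlo

The dip has no convenient closed-form null, so significance is empirical:
`simulate_null_dips(n, n_sims, seed)` draws `n_sims` standard-normal
samples of size `n` and reduces each to its dip; the p-value of an observed
dip is the proportion of null dips **strictly greater** than it. Because
the dip is affine-invariant, the normal's location and scale are
irrelevant, which is why the unspecified "normal distribution" of the null
is taken standard. One null serves every probe of a dataset (all share
`n`), so nulls are cached per `(n, n_sims, seed)` and can be serialized as
plain text. A zero count is stored as `p = 0` and rendered `"< 1/n_sims"`,
the honest Monte-Carlo resolution statement. Benjamini–Hochberg adjusted
values are reported alongside raw p-values; selection uses the raw
empirical p, which is how the marker panel was originally derived.

The default `n_sims` is $10^6$, the resolution needed to rank
transcriptome-wide scans. The test suite and the bundled benchmarks use
$10^4$ draws (and scans of 20–500 probes at $n = 47$ samples), which keeps
the full suite in the tens of seconds while leaving the 0.001 selection
threshold resolvable.

## Preprocessing conventions

The tool ingests probe-set-level matrices (e.g. MAS5-summarized); CEL
processing is out of scope. Choices that matter numerically:

* **Trimmed-mean scaling** (`trimmed_mean_scale()`): per array, discard
  `floor(0.02 * n)` values from each tail, rescale so the trimmed mean is
  150. Deterministic, idempotent, and exact to $10^{-9}$.
* **Intensity filter** (`intensity_filter()`): keep probes whose 90th
  percentile of log2 intensity strictly exceeds 6. Quantiles are always
  the type-7 (linear interpolation) convention; the 95th–5th spread
  diagnostic (`spread_90()`, kept under an honest name rather than "IQR")
  uses the same convention.
* **Flooring**: intensities are floored at 1 before log2 so the transform
  is defined for zeros in summarized data; the floor is configurable.
* **Order of operations**: scaling, then log2, then the filter. The
  reverse order is not equivalent; the order is configurable at the CLI
  but this default is what the package's own numbers mean.

## Discovery

`scan_bimodal()` computes per-probe dips on log2 intensities, empirical
p-values against the shared null, and BH-adjusted values. Candidates
require `empirical_p < alpha` (default 0.001) **and** a minor mode
fraction of at least 0.05. The floor is an interpretation of the "minor
allele frequency below 50%" selection idea: `min(f, 1-f)` is trivially
below 0.5, so the informative constraint is a lower bound that keeps
single-outlier probes out. Ranking is ascending empirical p, then
descending dip, then probe ID — fully deterministic. An `include` list
forces named probes into the candidate table, because panels may
deliberately carry a probe that narrowly misses the cut (the second
HLA-DQA1 probe set, 213831_at, with empirical p 0.006, is the canonical
example).

`suggest_threshold()` automates the visual cut-off choice: an exact 1-D
two-means split (exhaustive over the $n-1$ sorted splits) and the midpoint
of the two group means. For probes without bimodality evidence (dip p ≥
0.05) a two-means split is arbitrary, so the median is returned with a
fallback flag instead.

## Scoring and flagging

* A digit is 1 iff intensity **strictly** surpasses the probe's threshold.
  The default panel (`hla_panel()`) is 203290_at, 213831_at, 209728_at at
  128 each — the linear value of the log2 cut-off 7. Thresholds are
  per-probe because optimal cut-offs are tissue- and scaling-dependent.
* Within a donor the **majority** score is the reference; ties go to the
  earliest sample in annotation order (a deterministic stand-in for the
  informal "the other samples" reasoning).
* A discordant sample is `SOFT` when every discordant probe's intensity
  lies within ±1.0 log2 of its threshold — a slight transgression, not
  critical — and `HARD` otherwise. The band quantifies the observed
  contrast between a 1.5-fold transgression (not critical) and 10–46-fold
  discrepancies (possible mix-up); it is configurable.
* Sex calls (`call_gender()`) use a unanimous-panel rule over the REDKX
  transcripts (RPS4Y1, EIF1AY, DDX3Y, KDM5D high and XIST low ⇒ `M`; the
  reverse ⇒ `F`; anything else `ambiguous`). The decision thresholds are
  configuration, not published constants. A call contradicting the
  declared sex, or unambiguous calls disagreeing within a donor, adds a
  gender-mismatch reason and escalates to `HARD`; flags never de-escalate.
* `summarize_dataset()` counts `HARD` flags as "flagged" by default; a
  `SOFT`-only sample is reported but not counted, matching the "not
  critical" treatment of slight transgressions.
* `compatible_alleles()` interprets the two HLA-DQA1 digits against a
  packaged allele-by-probe match table (7 DQA1 alleles × 11 probes × 2
  probe sets). The table ships as static reference data; the underlying
  sequence alignment is not recomputed.

## The synthetic generator

`generate_dataset()` draws donor-level marker states (high with
probability `minor_allele_freq`), gives every sample of a donor its
donor's mode, and exports linear intensities. Defaults: modes 4 and 10 on
the log2 scale with sd 0.5, so the midpoint (7, linear 128) is the natural
threshold and planted markers at ~47 samples produce dips around 0.11 —
the regime real fingerprinting probe sets occupy; a donor-level high-state
probability of 0.3; four samples per donor; a unimodal background at the
midpoint. Mix-ups are **label** reassignments (`inject_mixups()`), never
intensity swaps, so the truth bookkeeping stays exact.

What the generator deliberately does not emulate: probe-level
hybridization physics, cross-hybridization, tissue effects on global
intensity, batch structure, or correlated probes. Passing the simulation
benchmarks therefore demonstrates the statistical machinery under the
model's assumptions, not performance on any particular real dataset.

### Benchmark design

Two benchmark constructions differ on purpose:

* **Recovery** uses probes planted with *exactly* 30% of samples in the
  high mode. Under donor-level Bernoulli states the realized minor
  fraction is itself random (binomial), and unbalanced draws — not the
  dip machinery — would dominate a tight recovery bound.
* **Power curves** vary the mode separation in log2 units at sd 0.5
  (i.e. 2σ, 4σ, 8σ): measured per-probe detection at $n = 47$, minor
  fraction 0.3, alpha 0.001 is ≈0 at 4σ, ≈0.92 at 8σ and ≈1 at 12σ. The
  dip test simply has no power at small separations for this sample size,
  which is why the benchmarks sit in the well-separated regime that
  haplotype-specific probes actually exhibit.
* **False positives**: for a calibrated scan, the expected candidate
  count among null probes is `n_probes * alpha`; the scan's selection is
  rank-based against the shared null, so this calibration is exact by
  exchangeability, with Poisson-scale fluctuations plus a shared-null
  correlation term (one null realization serves all probes of a dataset,
  as in the original procedure).

## Known limitations

* A $k$-probe panel spans only $2^k$ scores (8 for the default panel), so
  identical scores for different donors are expected — the score is
  *leaky* and detects mislabels only when the true scores differ; swap
  detection is reported conditionally and unconditionally for this
  reason.
* Thresholds transfer poorly across tissues and scaling pipelines;
  re-deriving them per tissue (or re-running `suggest_threshold()` on
  local data) is recommended.
* Reproducing the original transcriptome-wide counts (e.g. the 21,044
  probes entering the scan on the public training series GSE7753, or its
  marker dip values) requires downloading and MAS5-summarizing those
  arrays, which this package intentionally does not automate; the CLI
  documents the recipe instead.
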