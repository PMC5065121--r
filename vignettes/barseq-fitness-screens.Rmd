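---
title: "Pooled fitness screens by barcode sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled fitness screens by barcode sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
library(dplyr)
```

# The measurement

A pooled competition experiment mixes thousands of uniquely barcoded
yeast strains in a single nutrient-limited chemostat and lets selection
change their relative abundances over ~20 generations. Sequencing the
barcode amplicon at successive timepoints turns strain abundance into
read counts; the log-linear trend of a strain's relative frequency is
its fitness. `barseqfit` implements the whole computation — simulation
with known ground truth, exact-match barcode counting, regression
fitness, classification of the distribution of fitness effects (DFE) —
plus the downstream analyses that join a fitness screen to mutations
observed in evolve-and-resequence experiments.

## Dynamics model

Strain frequencies evolve by deterministic discrete-generation relative
growth,

$$ f_i(t) \;=\; \frac{f_i(0)\,(1+s_i)^t}{\sum_j f_j(0)\,(1+s_j)^t}, $$

where $s_i$ is the per-generation selection coefficient relative to a
reference ($s=0$ neutral). Drift is deliberately omitted: chemostat
pools hold on the order of $10^9$ cells, so stochastic frequency
changes are negligible against selection on the scale measured here.
De-novo mutation during the 20-generation competition, PCR bias, and
sequencing error models are likewise out of scope; sequencing noise is
modeled as a single multinomial draw of the sample's read depth over
the true frequencies.

## What the generator emulates — and what it does not

`build_pool()` + `simulate_competition()` reproduce the screen's stated
conditions: samples every 3 generations from generation 0 through 20,
two replicate competitions, and an expected depth of 462 reads per
strain per sample. The default DFE is 90% neutral strains, 5%
deleterious with $s \sim U(-0.3, 0)$ and 5% beneficial with
$s \sim U(0, 0.4)$, spanning the effect range a nutrient-limited yeast
screen observes; a control pool is the same machinery with a point mass
at $s = 0$. Timepoint 0 is the sample taken at the switch to continuous
culture; the batch phase before it is not modeled, and sampled
generations are taken at exactly 3-generation spacing (real dilution
rates make them approximate).

Reads are emitted as 36-base single-end records laid out as a 6-base
sample tag, a 10-base constant spacer standing in for the common primer
sequence, and the 20-base strain barcode. The real assay encodes the
multiplex tag in the PCR primer and does not pin down the read layout;
fixing one makes counting exactly testable, and the counter's offset is
configurable for other layouts. Qualities are constant placeholders
("I"): the counting rules use no quality information.

Because the generator is deterministic given a seed and noise enters
only in the multinomial draw, a passing recovery test demonstrates the
*computational* pipeline — it does not validate against real-data
artifacts such as PCR jackpots, barcode cross-contamination, or strains
whose true fitness drifts with pool composition (frequency-dependent
selection).

## Counting rules

Counting is exact-match on both ends, mirroring the screen's processing
rules:

* a read belongs to a sample iff its first 6 bases equal a multiplex
  tag exactly;
* a read increments a strain iff its barcode substring equals the
  catalog barcode exactly — one mismatch discards the read;
* barcodes shared by more than one catalog entry are removed before
  counting and their reads tallied as *ambiguous*;
* strains with fewer than 20 summed counts across the samples of a
  screen are dropped (strict: a row sum of exactly 20 is kept). "Across
  the samples" is read as the row sum over all samples passed to
  `filter_counts()`, i.e. one condition's replicate set when used
  inside `fit_fitness()`; both the threshold and the grouping are
  arguments.

Per sample, `assigned + unassigned + ambiguous = demultiplexed` is an
invariant the test suite enforces, and the production counter is
checked against a naive per-read linear scan.

## Fitness estimation

Counts are converted to frequencies after adding a pseudocount of 10 to
every barcode (avoiding zeros), log2 ratios are taken to the
generation-0 sample, and an ordinary least-squares slope on generation
is fit using only generations 6 through 20 — the window in which the
culture is at steady state. The two replicate slopes are averaged;
strains present in one replicate keep that value. Fitness is therefore
reported in log2 per generation. Choices worth noting:

* the normalization denominator is the pseudocount-incremented total;
  raw-total normalization only rescales each sample and cancels in the
  slope;
* the generation-0 reference point (log ratio 0) is *not* part of the
  regression by default (`include_t0 = TRUE` adds it);
* the window is closed at both ends, so the generation-20 sample is
  included;
* the reported fitness is the raw slope, uncentered. A pool's mean
  fitness grows as beneficial strains expand, which adds a common
  negative trend to every other strain's relative frequency; the
  measurement is *pool-relative*. `center = "control"` (median of a
  control collection) or `center = "median"` re-anchors the scale to
  neutrality when an absolute comparison is wanted;
* fitness values are slopes, not $2^{\text{slope}}-1$ percentages; at
  the ±10% cutoff scale the two conventions differ by little, and the
  raw-slope convention is used throughout.

Slopes are computed as $\mathrm{cov}(t, y)/\mathrm{var}(t)$ vectorized
over strains (every strain shares the design), verified against
`lm()` in the tests.

### Known limitation: pseudocount saturation

The pseudocount that protects against zeros also *floors* the
frequencies of strains whose counts fall well below 10 per sample. In a
pool where strong beneficials sweep (the default mixture multiplies the
normalizing denominator ~8-fold by generation 20), neutral strains end
near 50 expected reads and strongly deleterious strains near zero — so
their log-ratios saturate and their slopes are compressed toward the
floor, non-monotonically in $|s|$. Noise-free analysis of the default
2,000-strain pool at 462 reads/strain puts the Pearson correlation
between estimated and true fitness at ~0.85, with most of the loss in
the deleterious tail; the same estimator at 10× depth reaches ~0.97,
and the test suite checks that deeper sequencing strictly reduces the
recovery error. When absolute recovery of strong deleterious effects
matters, raise the depth or lower the pseudocount; the defaults stay at
the screen's published values.

## DFE classification

The beneficial/deleterious cutoff of ±0.10 is calibrated on the control
collection: `control_window_fraction()` reports the share of control
strains inside the window (98%+ in a well-behaved screen, and ≥95% in
the simulated all-neutral pool). Classification is strict — a value of
exactly ±0.10 is neutral — because the downstream reporting convention
is "fitness > 0.10". `dfe_summary()` reports class counts per condition
(strain × condition events *and* deduplicated strains, since both
conventions appear in summaries of such screens), cross-condition
overlap of beneficial strains, and a 2×2 chi-square (uncorrected by
default; `correct = TRUE` available) of each test collection against
the control for beneficial and deleterious enrichment.

## Evolve-and-resequence catalog analyses

The mutation catalog holds one record per (gene, sample) mutation event
with ploidy, sample type (sequenced clone vs whole population),
condition and a ten-class mutation vocabulary that maps onto
SNPeff-style impacts (high / moderate / low / modifier). The analyses
are:

* **Recurrence** — distinct mutated samples per gene; genes hit in >1
  sample are recurrent.
* **Ploidy contingency** — per-class 2×2 (class vs rest × haploid vs
  diploid) tested by chi-square with Yates continuity correction
  (Fisher by flag), and an overall class × ploidy heterogeneity test by
  Fisher's exact test with Monte Carlo fallback for large tables. Yates
  is the default because the per-class tables are sparse in the diploid
  column and the corrected test reproduces the published stop-gained
  signal (p ≈ 0.003 at counts 118/1017 haploid vs 5/150 diploid).
* **Gene-length bias** — two-sided Wilcoxon rank-sum comparing lengths
  of recurrent vs singleton genes, the standard caveat for
  recurrence-based driver calling.
* **Driver prediction** — a mutation is `predicted_beneficial` when its
  gene reached fitness ≥ 0.10 in *any* collection in the *same*
  condition (≥ 0.05 is `intermediate`). Matching is deliberately at
  gene level across collections; a strict mode restricting high-impact
  mutations to deletion collections and modifiers to amplification
  collections exists but is off by default, since there is no principled
  one-to-one map between mutation type and collection. Both max- and
  mean-across-collections summaries are available
  (`statistic = "max"`/`"mean"`) because reported per-sample driver
  burdens are compatible with either convention.
* **Per-sample burden** — driver and total mutation counts and their
  ratio per sample, group means for clones vs populations, and a
  rank-sum comparison of the ratios.
* **Found vs not-found** — among screen-beneficial genes in one
  condition, compares fitness of those actually mutated in evolution
  experiments against those never observed, with optional exclusion of
  a dominant driver gene.

All rank and exact tests are `stats::` routines; the test suite checks
them against exact enumeration (hypergeometric sums, full rank-sum
permutation) for small groups.

## Selection dynamics and the 10% cutoff

The ±10% cutoff is not arbitrary: deterministic haploid selection
$p_{t+1} = p_t(1+s)/(1+p_t s)$ implies a lineage with $s = 0.10$
founded by one cell in $10^9$ needs

```{r dynamics}
sc <- selection_scenario(s = 0.10, N = 1e9, p0 = 1e-9)
time_to_frequency(sc, 0.05)
fixation_time(sc)
```

generations to reach 5% and to fix (fixation operationalized as
frequency $1 - 1/N$; the published rules of thumb, ~200 and ~500, are
upper bounds of these). Mutations much below 10% would rarely surface
within the few hundred generations of a typical evolution experiment.
The closed-form odds solution and per-generation iteration agree
exactly, and both are exposed.

## Numerical and degenerate-input choices

* Frequency propagation works in log space, so strong selection over
  many generations cannot overflow, and outputs are renormalized to sum
  to 1 within 1e-12.
* Frequencies of exactly 0 are propagated as 0 (a strain absent from
  the pool stays absent).
* `estimate_fitness()` refuses windows with fewer than two distinct
  timepoints; `log_ratios()` refuses non-positive frequencies and
  points at the missing pseudocount.
* Classification boundaries are strict on both sides; chi-square
  enrichment on a class absent from both groups returns statistic 0 and
  p = 1 rather than NaN.
* All randomness (pool construction, multinomial sequencing, Monte
  Carlo Fisher) flows through R's RNG; `seed` arguments use
  `withr::with_seed()` so nothing perturbs the caller's RNG state.
* Problem sizes in the test suite are the screen's stated conditions
  where a check targets them (2,000 strains at 462 reads/strain for
  recovery and control calibration) and small fixtures everywhere
  correctness is exactly enumerable.

## Interfaces

Every stage takes and returns tibbles, so stages chain with the pipe;
`run_pipeline()` ties them together from a single config list and
writes TSVs with provenance headers (version, seed, parameters) that
round-trip losslessly through the package readers. FASTQ is read and
written via Biostrings. `tidy()`/`glance()` expose fit objects
broom-style, and `plot_dfe()`, `plot_trajectory()`,
`plot_recurrence()` and `autoplot()` give quick ggplot2 views.
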