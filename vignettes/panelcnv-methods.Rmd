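---
title: "Methods: coverage normalization, QC and CNV calling in panelcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage normalization, QC and CNV calling in panelcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcnv)
```

## The problem and the model

Targeted hybrid-capture panels sequence a few hundred to a few thousand exons
at high depth. The read depth observed over one exon is the product of three
things: the sample's overall sequencing depth, the exon's capture efficiency
(a stable property of the bait), and the sample's copy number at that locus.
panelcnv isolates the third factor by two normalizations, both computed
within a *batch* — the set of 7–10 samples captured in one multiplexed pool
and sequenced together, which therefore share capture conditions.

1. **Fractional coverage.** Each sample's per-interval total coverage is
   divided by that sample's summed coverage over the panel. This removes
   overall depth: the fractions of a sample sum to 1 and are invariant to
   rescaling its raw totals.
2. **Batch-median log2 ratio.** Each interval's fraction is divided by the
   median fraction for that interval across the batch, and the ratio is
   taken to log2. Under the assumption that most samples are diploid at any
   one interval, the batch median estimates the two-copy reference, so

   $$r_{si} = \log_2\!\frac{f_{si}}{\mathrm{median}_s\, f_{si}}$$

   reads directly in copy-number units: 0 for two copies, $\log_2(3/2)
   \approx 0.58$ for a single-copy gain, $-1$ for a single-copy loss. The
   estimated absolute copy number of a called segment is
   $\widehat{CN} = 2 \cdot 2^{\tilde r}$ with $\tilde r$ the segment's median
   ratio.

Because the reference is the *median of co-captured samples*, the method has
two structural blind spots worth keeping in mind: a CNV shared by half or
more of the batch is invisible (it becomes the reference), and a sample's own
large CNV slightly shifts all of its other ratios through the fractional
denominator (a 3-interval deletion on a 400-interval panel displaces the rest
of that sample by under 0.01 log2 units — visible in the noiseless checks
below, irrelevant at realistic noise).

## X-chromosome correction and sex inference

X-interval fractional coverage differs about two-fold between sexes, so
relative to a mixed-sex batch median, males sit near $-1$ and females near
$0$ (or both are offset when the batch is unbalanced). panelcnv summarizes
each sample's X intervals by a trimmed median (the highest and lowest 10% of
X probes are discarded first, so a handful of erratic baits or a real X CNV
does not drag the summary), then partitions the per-sample summaries around
two medoids. With at most ten samples per batch the 2-medoid problem is
solved *exactly* by exhaustive search over medoid pairs, minimizing total
absolute deviation — no iterative heuristic, which makes the step fully
reproducible and testable against brute-force partition enumeration (and, in
the test suite, against `cluster::pam`).

The cluster with the lower medoid is labelled male (one X against the batch
reference), the other female. Each sample's X ratios are then re-centered by
subtracting its cluster's median summary, so X calls read on the same scale
as autosomal calls — *relative to the sample's own expected X dosage*. When
the two medoids are separated by less than 0.3 log2 units
(`x_min_separation`) the batch is treated as single-sex: one cluster, a
single global re-centering, and `predicted_sex = "indeterminate"` for
everyone, since coverage alone cannot tell an all-female batch from an
all-male one. The 0.3 default sits between the ~0 separation of a single-sex
batch and the ~1 separation of a mixed batch; both the trim fraction and the
separation threshold are configurable because neither has a canonical value.

A deliberate asymmetry: autosomal ratios are *not* corrected for the small
complementary offset that sex composition induces there (males devote ~2–3%
less coverage to X and correspondingly more to autosomes). This keeps
autosomal ratios strictly interpretable as "versus batch median"; the effect
is an order of magnitude below the calling thresholds.

## Sample quality control: the whisker rule and the iteration loop

Per sample, a five-number summary is computed over all unmasked log2 ratios:
Tukey hinges for Q1/Q3 (`grDevices::boxplot.stats` with `coef = 3`) and
whiskers at the most extreme *data values* within Q1/Q3 ± 3×IQR. A sample
fails QC when either whisker extends strictly beyond the theoretical
single-copy bounds (+0.58 / −1): such a distribution is too dispersed to
separate single-copy changes from noise, and worse, the sample would distort
the batch median for everyone else. Failing samples are therefore removed
and the survivors re-normalized as a fresh batch; the loop repeats until an
iteration fails no one. Each iteration's matrix, QC table and batch boxplot
are written to `iteration_k/` directories for review. The loop terminates in
at most $n$ iterations since every continuing iteration removes at least one
sample; if fewer than `min_pass_samples = 3` survive, the whole batch is
failed — a median over two samples is not a reference.

QC is evaluated on the X-corrected matrix of each iteration. The ordering is
not forced by the mathematics (an uncorrected mixed-sex batch would fail
every male on the X block alone, which argues for correcting first); it is
configurable via `qc_on_corrected`. Masked intervals (zero batch median) and
floored values (zero sample coverage at a live bait, mapped to −10 rather
than −∞) are excluded from the summary so a single dead bait cannot fail a
sample.

## Calling: the dual-threshold rule

An interval is *gain-eligible* when its ratio strictly exceeds **both** the
fixed gain threshold (0.40) and the sample's upper whisker; *loss-eligible*
when strictly below both the fixed loss threshold (−0.55) and the lower
whisker. The fixed thresholds encode a clinically validated sensitivity
point; the whisker condition adapts to each sample's own dispersion so a
noisy-but-passing sample does not spray single-point calls. Maximal runs of
consecutive same-type eligible intervals on one chromosome become calls;
masked intervals break runs. All comparisons are strict — a value exactly at
a threshold is not eligible — matching the QC convention.

`min_probes_gain`/`min_probes_loss` default to 1: single-exon events are
real and clinically relevant, and the dual condition already suppresses most
single-point noise. Laboratories that prefer a multi-probe rule for losses
can raise `min_probes_loss`. A user-supplied exclusion list of exon labels
drops single-interval calls in exons known to fail NGS analysis — this list
is laboratory-specific knowledge, not something the tool infers.

Two annotations support review rather than filtering: a call is **recurrent**
when the identical event (same chromosome, rank span and type) occurs in
more than `cohort_recurrence_fraction = 1%` of cases — likely a polymorphism
or capture artifact — and **GC-flagged** when every member interval has
user-supplied GC content below 0.35 or above 0.65, where capture is least
reproducible. Both flags are carried in the output, never silently applied;
`drop_recurrent` removes flagged calls from the written table for workflows
that want the filtered view. Within one run recurrence is computed over that
run's cases; `merge_cohort_calls()` pools call tables across runs to compute
laboratory-scale frequencies.

## ddPCR confirmation calculator

Orthogonal confirmation by droplet digital PCR compares a target locus
against an *RPP30* reference, itself controlled against *AP3B1*. The raw
copy number is divided by a sample-specific Reference Correction Constant,
$RCC = 2 \times (AP3B1{:}RPP30)$, and rescaled by `rcc_scale = 2` so that a
perfectly calibrated sample (reference ratio 1) keeps its raw value — the
unscaled division would halve it, and the intended scale of the published
constant is ambiguous, so the restoring factor is exposed as configuration.
Verdicts are loss below 1.5 and gain above 2.5 normalized copies; samples
with an RPP30:AP3B1 ratio outside 0.9–1.2 are flagged for manual review
because the reference genes themselves may be copy-variable.

## What the simulator emulates — and what it does not

`simulate_batch()` generates a batch as: per-interval capture efficiency
$e_i \sim \mathrm{lognormal}(0, 0.5)$; expected total coverage
$\mu_{si} = d \cdot w_i \cdot e_i \cdot (CN_{si}/2) \cdot
\mathrm{dosage}_{si}$ with mean depth $d = 724$, interval width $w_i$, and
dosage halving X intervals in males; observed totals
$\mathrm{round}(\mu_{si} \cdot 2^{\varepsilon})$, $\varepsilon \sim
N(0, \sigma)$ with $\sigma$ = `noise_sd` = 0.1 *in log2 units* — the scale
on which every threshold in the pipeline is stated. Defaults mirror a
realistic clinical batch: 8 samples, a 1,016-exon panel, alternating sexes.
High-dispersion (QC-failing) libraries are modelled by multiplying a
sample's noise SD by 6; erratic baits by multiplying 1% of intervals' noise
by 4. Multiplicative lognormal noise is the primary model because at
clinical panel depths (hundreds-fold) capture-efficiency variation dominates
counting noise; a Poisson layer is available behind `poisson = TRUE`.

The simulator deliberately omits features of real capture data: GC-dependent
coverage bias curves (erratic baits are placed at random, not at GC
extremes), mappability artifacts, correlated noise along the genome,
batch-to-batch efficiency drift, and read-level effects. Passing tests on
simulated batches therefore demonstrate the *algorithmic* contract —
normalization arithmetic, QC dynamics, segmentation correctness, recurrence
accounting — not clinical sensitivity on real libraries, which depends on
exactly the artifacts the simulator idealizes away.

Two simulator-vs-theory subtleties are asserted with explicit tolerances in
the tests rather than exactly. First, an injected deletion shrinks the
carrier's total coverage, so its noiseless ratio is
$-1 + \log_2 \frac{T}{T - D/2}$ (with $T$ the expected total and $D$ the
deleted portion) — about +0.005 for a 3-interval event on a 400-interval
panel. Second, integer rounding of totals adds jitter below $10^{-3}$ log2
units. Both are properties of the method's fractional normalization, not
simulation error.

## Numerical choices and degenerate inputs

* Zero batch-median intervals are masked (`NA`) and excluded everywhere;
  zero sample coverage at a live bait floors at −10 log2 units.
* Tie-breaks: the exhaustive medoid search keeps the first optimum at a
  cost tolerance of $10^{-12}$; equidistant points join the lower medoid.
  In 1-D, even-sized clusters have two equal-cost medoids, so tests compare
  costs, not medoid identity.
* The ddPCR QC window is evaluated with $10^{-9}$ slack to absorb float
  error in reciprocal reference ratios.
* Batches need ≥3 samples to normalize, ≥5 finite values per sample to
  summarize; both are hard errors with typed conditions.
* Fewer than 2 distinct X summaries, or missing X intervals, degrade the sex
  step gracefully (single cluster / skipped) rather than erroring.

## Problem sizes used by the test and acceptance runs

The shipped checks use 400-interval panels (50 batches for parameter
recovery, 1,000 random 50-interval vectors for the segmentation oracle, all
batch sizes 2–8 for the clustering oracle, a 200-case cohort in 25 batches
for the recurrence filter). These sizes give stable statistics while keeping
a full run in tens of seconds; the pipeline itself is routinely run at
1,000+ intervals (the simulator's default panel size).

## Known limitations

* Sensitivity for duplications is intrinsically lower than for deletions:
  the gain landmark (0.58) sits closer to the noise floor than the loss
  landmark (−1), and the whisker condition tightens it further when a
  duplication's own points inflate the upper whisker. At noise SD 0.1 the
  interval-level recovery of 4-exon events is ~100% for deletions and ~91%
  for duplications (~95–96% combined).
* Common CNVs (carried by ≥ half the batch) are invisible by construction.
* Breakpoints are resolved only to target-interval boundaries; no
  statistical significance is attached to calls — thresholds are empirical.
* Sex-chromosome aneuploidies appear only through ordinary calling on the
  corrected X (e.g. an XXX-like sample shows a gain relative to the female
  cluster); there is no dedicated detector, and the Y chromosome is not
  handled.
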