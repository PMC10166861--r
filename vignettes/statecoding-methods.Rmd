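---
title: "Methods: state coding of prefrontal spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state coding of prefrontal spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statecoding)
```

## The scientific problem

Prefrontal (prelimbic) neurons participate both in the long-term recall of
learned fear and in the experience of tonic pain. Given tetrode recordings
of the same units across three behavioral sessions — a neutral baseline
context, a tone-cued fear-recall session with intermittent freezing bouts,
and a capsaicin-induced tonic-pain session with intermittent nocifensive
bouts (paw lifting, licking, flinching) — the analysis asks, unit by unit:

1. Does the unit's *global* mean firing rate change in fear or pain
   relative to the neutral context, beyond what repeated exposure to the
   *same* state would produce?
2. Is the unit's firing *time-locked* to the behavioral episodes
   themselves (freezing, nocifensive bouts)?
3. Is the unit a putative principal (excitatory) neuron or an
   interneuron, judged from its waveform and rate?

A companion module quantifies dual-label (Fos + activity tag)
co-labeling in cell-count tables and its chance level, the histological
counterpart of the same overlap question.

`statecoding` implements the full chain — signal conditioning, spike
detection, duplicate pruning, both classifiers, cell typing, overlap
statistics — together with a ground-truth synthetic-data generator, so
every stage is testable without access to recordings.

## Signal conditioning and spike extraction

Raw multi-channel traces are conditioned in the order: per-sample
**common-median subtraction** across channels (removes shared artifacts),
then a **zero-phase fourth-order Butterworth bandpass, 300–6000 Hz**
(`signal::filtfilt`; forward–backward filtering preserves spike shape,
which matters because waveform features feed cell typing). Spikes are
events whose absolute amplitude exceeds **9 × the per-channel raw median
absolute deviation**; for Gaussian noise this is ≈ 6.07 noise sigmas, so
chance crossings are vanishingly rare. Each supra-threshold run yields one
event at its signed extremum, a 1-ms per-channel dead time suppresses
re-triggering, and 2-ms snippets centered on the extremum are kept.

The MAD is computed over the whole session per channel: the estimator is
robust to the spikes themselves, and a session-wide window gives the
lowest-variance threshold available without modeling nonstationarity.

Why the order median → bandpass and not the reverse: with a small number
of channels the per-sample median is itself noisy, and subtracting it
*after* filtering leaves a leptokurtic residual — its MAD shrinks more
than its tails, so an adaptive MAD threshold admits false events.
Referencing first lets the bandpass smooth that artifact away. The test
suite asserts that recall of true spikes is unaffected by the order, while
the false-event behavior is exactly why the canonical order is fixed.

**Duplicate pruning.** Tetrode groups can register one neuron on
neighboring channel groups. Pairs of units sharing more than 10% of spike
times are flagged — "shared" means within ±0.5 ms (exact sample-tick
equality is brittle at 30 kHz), and the fraction is taken over the
*smaller* unit's spike count, the conservative denominator. Within each
flagged pair the unit with the higher fraction of inter-spike intervals
below 2 ms (refractory violations, a contamination signature) is removed,
iterating until no pair exceeds the threshold; iteration makes the
operation idempotent. Full spike sorting (assignment of events to units)
is out of scope: the pipeline consumes sorted unit tables, or ground-truth
assignments from the simulator.

## Global rate coding against a same-state null

The null question is: how much does a unit's mean rate change when the
*same* state is merely repeated? From paired same-state sessions (in the
study design, repeated neutral-context and repeated fear-retrieval
sessions; in the simulator, the paired baselines), each unit contributes
`L = log(r2 / r1)` of its mean rates; the pooled distribution is
approximately normal and centered on 0, and its standard deviation σ sets
the global threshold at **2σ**. A unit is then called *increased* in fear
(or pain) if `log(r_state / r_baseline) > 2σ`, *decreased* below −2σ.
Categories combine the per-state directions: change in one state only
(state-specific), in both (common), or neither.

Rates are measured over 4 min of baseline, 7 min of fear recall, and the
first 3 min after capsaicin injection (the window where tonic pain builds
and is maintained).

Numerical choices:

* Natural log; any base is consistent as long as threshold and ratios use
  the same one.
* Units with a rate below 0.05 Hz in either session of a pair are
  excluded from null fitting, and units with sub-threshold baselines are
  flagged unclassifiable rather than epsilon-padded — log ratios of
  near-silent units otherwise dominate σ.
* σ is computed about the sample mean, not about 0: forcing the center
  inflates σ when slow drift exists. A warning fires if the pooled mean
  strays beyond σ/2, as a data-quality signal.
* Fewer than 10 usable pairs is refused outright: a 2σ threshold from a
  handful of units is noise.

## Behavior-episode-locked coding

Freezing and nocifensive behavior are intermittent, so a unit can code
the *episodes* without shifting its session-mean rate. Spike rates are
binned with a **0.8-s sliding window advanced in 0.4-s steps**; a bin
belongs to the behavior-matched group iff its onset *and* offset fall
inside one episode, to the outside group iff both fall outside all
episodes, and is excluded when it straddles a boundary. Each unit's
in-episode bin rates are compared with the binned rates of the whole
unstimulated baseline session by a **randomized permutation test**:
pooling both groups, re-splitting at the original sizes 10,000 times, and
computing the one-sided `p = (1 + #{null ≥ observed}) / (n_perm + 1)`.
The effect size is the standardized mean difference with pooled-s.d.
denominator. A unit is significant for a state at `p < 0.001` and
`effect > 0.5`; fear-only, pain-only, both (common) and neither
(unspecific) categories follow. For heat-map display, binned rates are
normalized to the baseline-session mean, so normalized baseline bins
average exactly 1.

Design choices worth stating:

* The tested contrast is in-episode bins vs baseline-session bins; bins
  outside episodes within the state sessions are retained and reported as
  a secondary contrast but do not enter classification.
* The test is one-sided for increases; rate decreases are visible in the
  global classifier but are not behavior-categorized.
* The strict `α = 0.001` is the default (a `0.05` variant exists as an
  argument), and with 10,000 permutations the smallest attainable p-value
  (1/10,001) resolves it comfortably.
* Overlapping bins are statistically dependent; the permutation unit is
  nevertheless the bin, matching the published analysis. A block
  permutation option (blocks of ⌈width/step⌉ bins) is available for users
  who want strict exchangeability; it is off by default. The dependence
  has a quantifiable consequence: adjacent bins share half their window,
  so bin counts carry a lag-1 correlation of exactly 0.5, the observed
  mean difference has about twice the variance the pooled permutation
  null assumes, and gain-1 p-values are therefore *not* exactly uniform
  (their CDF follows the √2 variance-inflation prediction). With iid
  inputs the test's p-values are uniform, and at the strict
  `p < 0.001` + `effect > 0.5` classification rule the realized
  false-positive rate on null units remains far below 0.5% despite the
  inflation — the effect-size gate is what makes the published rule
  robust to the dependence.

## Cell typing

Three features per unit — half-amplitude duration (width of the trough at
half its depth, ms), trough-to-peak time (ms), and mean firing rate (Hz)
— are z-scored and clustered by **Ward linkage on Euclidean distances**
(`hclust(method = "ward.D2")`, the Ward criterion on unsquared Euclidean
input), cutting the tree at the two most prominent clusters. The cluster
with the *narrower* trough-to-peak and the *higher* mean rate is called
interneuron — the standard cortical convention, which the source analysis
leaves implicit. If the two criteria disagree the waveform criterion
wins and the result is flagged ambiguous. Constant feature columns are
dropped with a warning (they carry no information and break z-scoring).

## Overlap quantification

For a count table (per region: Fos⁺, tag⁺, double⁺, DAPI, volume):

* chance overlap = `(Fos⁺/DAPI) × (tag⁺/DAPI) × 100%` — the expected
  double-positive percentage under independent labeling;
* observed overlap = `100 × double⁺ / tag⁺` (or `/ Fos⁺`; both framings
  are reported in the literature and both are supported);
* densities are counts over volume (cells/mm³).

The projection-image intensity binning maps pixel values 0–255 onto nine
levels (10-wide bins to 50, then 50-wide to 200, top bin closed at 255).
Bin edges are lower-inclusive; the published description ("between 10 and
20") does not fix edge inclusivity, so one convention is chosen and
tested at every edge.

## The synthetic-data generator

The generator's job is to emulate the statistical structure the analysis
*assumes*, with known ground truth:

* **Spiking**: homogeneous Poisson per unit, with a piecewise-constant
  gain (default ×3) inside behavioral episodes of the unit's matched
  state(s); common units gain in both states, unspecific units never.
  A 2-ms absolute dead time (default on) makes refractory bookkeeping
  meaningful. Spike times are strictly increasing by construction.
* **Episodes**: alternating exponential on/off bouts (mean bout 5 s,
  duty cycle 0.3 by default), truncated at session boundaries, with the
  initial phase drawn from the stationary occupancy. Bout-length
  distributions for freezing/nocifensive behavior are not described in
  the source analysis; the exponential is a stand-in chosen for its
  simplicity, not an inferred fact.
* **Sessions**: 300 s baseline (plus a paired second baseline for null
  calibration), 420 s fear, 300 s pain by default, mirroring the 4/7/3-min
  analysis windows they contain.
* **Base rates**: uniform on 2–6 Hz. This is deliberate: the pooled 2σ
  same-state null presumes a roughly homoscedastic, normal pooled
  log-ratio distribution, and Poisson counting noise gives
  `var(L) ≈ 2/(rate × T)`. A rate range spanning a decade or more turns
  the pooled null into a heavy-tailed scale mixture whose 2σ two-tail
  mass exceeds the nominal ≈4.6% no matter how correct the code is; a
  moderate ~3× band keeps the pooled null near-normal (analytically
  ≈5% flagged at 2σ) while staying within physiological sustained rates.
* **Waveforms/phenotypes**: interneuron probability 0.115 (matching the
  reported ~30/261 split); features drawn per phenotype from Gaussians —
  principal: half-amplitude 0.30 ± 0.05 ms, trough-to-peak 0.65 ± 0.12 ms,
  rate 2.5 ± 1.5 Hz; interneuron: 0.15 ± 0.05 ms, 0.29 ± 0.12 ms,
  10 ± 2.5 Hz — about 3 cluster-s.d. separation per feature.
* **Voltage traces**: white Gaussian noise plus biphasic templates
  (Gaussian trough whose half-depth width *is* the designed
  half-amplitude duration, delayed positive bump at the designed
  trough-to-peak) with amplitudes expressed in noise-sigma multiples.
* **Count tables**: Poisson counts around density expectations;
  independent labeling by default, or an imposed double-positive fraction.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: no local field potentials or oscillatory
structure, no spike-waveform drift or electrode movement, no
cross-correlation between units, no rate nonstationarity outside
episodes, no overdispersion relative to Poisson. Real recordings violate
several of these (cortical counts are typically overdispersed), so the
calibration figures here are statements about the method under its own
assumptions, not performance guarantees on tissue.

Determinism: every stochastic function takes a seed and produces
bit-identical output for identical inputs; all writers emit byte-identical
files (6-decimal fixed formatting for seconds).

## Problem sizes used in validation

The shipped validation uses sizes a desk machine handles in minutes:
1,000 gain-1 units for null calibration (expected flagged fraction
≈4.6% ± sampling error), 500 gain-1 units × 10,000 permutations for
behavior-locked type-I control (non-unspecific rate ≤ 0.5%; see the
binning section for why exact p-value uniformity is not expected under
overlapping bins), 200 units (50 per class, gain 3, duty 0.3, 300-s
sessions) for category recovery (≥90% both classifiers), a 60-s
4-channel 30-kHz trace with 10σ templates at 5 Hz for detection
(recall ≥99% within ±0.5 ms, false events ≤0.1 Hz, MAD-σ within 2%),
and ≤1,000-spike constructed sets for exact dedup-oracle equivalence.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_units = 40, episode_gain = 3, seed = 1L)
sim <- generate_unit_sessions(cfg)

glob <- code_global(sim$spikes)
table(glob$classification$category)

behav <- code_behavior(sim$spikes, sim$timelines,
                       session_durations = cfg$session_durations,
                       n_perm = 2000, seed = 2L)
table(behav$classification$category, sim$truth$class)

fm <- generate_feature_matrix(200, cfg, seed = 3L)
table(classify_cell_types(fm$features), fm$phenotype)
```

## Known limitations

* The same-state σ is estimated from the synthetic paired baselines in
  `code_global()`; a drifting preparation would need the same-state
  sessions the study design provides (repeated neutral/fear sessions),
  and the mean-offset warning is the only drift diagnostic.
* Overlapping sliding-window bins are dependent; the default permutation
  test inherits this from the published design. Use `block` in
  `permutation_test()` for a conservative variant.
* The dedup rule is pairwise and greedy (worst pair first); pathological
  chains of near-duplicates could in principle depend on processing
  order, which the iterated worst-pair rule makes deterministic.
* Detection assumes stationary noise within a session; MAD is estimated
  session-wide.
```
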