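---
title: "Imaginary-coherence brain networks: models, parameters and design choices"
author: "imcohnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaginary-coherence brain networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the estimators, the statistical machinery, the synthetic data they are
validated on, and the choices made where the design was genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

A tactile-stimulation EEG experiment records multichannel scalp signals
under two conditions (rest baseline, fabric stimulation of one forearm),
over both forearms, in two subject groups. The scientific questions are
(i) which channel-pair couplings the stimulation induces (and how
lateralized they are relative to the stimulated forearm), and (ii) how
the functional brain network's multiscale structure differs between
stimulated limbs within each group.

The pipeline is: signal conditioning → imaginary-coherence connectivity
→ cluster-permutation extraction of stimulation-induced connectivity
(SFC) → per-subject binary networks and graph indices → group
statistics.

## Signal conditioning

Continuous recordings pass through a fixed chain: band-pass, average
reference, epoching, an artifact hook, and an optional mid-sagittal
flip.

**Band-pass (1–45 Hz default).** The filter is zero-phase (forward–
backward), so the 2-s coherence windows are not skewed by group delay.
A single 4th-order Butterworth band-pass cannot attenuate 55 Hz by
40 dB when the band is as wide as 1–45 Hz at 1000 Hz sampling, and a
high-order band-pass in transfer-function form is numerically fragile
at a 0.002 normalized low edge. `bandpassFilter()` therefore cascades a
4th-order Butterworth high-pass (one forward–backward pass) with a
6th-order low-pass applied twice. Closed-form Butterworth magnitudes
give, for the (1, 45) band: ≤ −48 dB at 0.5 Hz, ≤ −43 dB at 55 Hz,
≤ −60 dB at 60 Hz, and within 1 dB of unity through the band interior;
the test suite confirms these against sinusoids and the analytic
response. Channel means are removed first, so DC vanishes exactly.

**Average reference** subtracts the instantaneous channel mean
(idempotent; requires ≥ 2 channels). **Epoching** keeps `retainS`
(default 12 s) from each condition-annotation onset and cuts half-open
4-s windows, giving 3 epochs per annotation at defaults. The **artifact
hook** is a pluggable `TrialSet -> TrialSet` strategy (identity by
default) with a deterministic amplitude-threshold rejector provided;
this replaces manual visual inspection for reproducibility. The module
contract types the hook on epoched trials, so the chain epochs before
rejecting — the one place where two statements of the stage order in
the design brief disagreed, resolved in favour of the typed contract.
The **mid-sagittal flip** permutes each channel to its left/right
homologue (C3↔C4, z-line fixed), the standard device for pooling
subjects with left- and right-hemisphere lesions; it is an involution,
tested bitwise.

## Connectivity: imaginary coherence

For one trial, `crossSpectrum()` forms Welch-averaged cross-spectra
with 2-s Hann-tapered segments at 50% overlap: a 4-s trial yields 3
segments and a 0.5-Hz grid. Coherency is the normalized cross-spectrum
`C_ij(f) = S_ij / sqrt(S_ii S_jj)`; the connectivity value is
`|Im C_ij(f)|`. A source reaching two electrodes by volume conduction
arrives with zero lag, making its coherency real — the imaginary part
discards exactly that component, which is why this estimator is used
instead of magnitude coherence.

Choices the estimator definition leaves open:

* **Absolute value.** The imaginary part is signed; the pipeline's
  weighted 0–1 connectivity takes `|Im|`, and the signed values are
  retained in a slot for diagnostics and the DFT oracle tests.
* **Trial handling.** Cross-spectra are averaged across the segments of
  each trial; condition-level connectivity averages per-trial ImCoh (not
  cross-spectra), because the trial-wise values are what the per-subject
  paired t-tests consume. Averaging cross-spectra first is available by
  passing pooled segments, but is not the default.
* **Band edges inclusive.** Beta 2 = 20–25 Hz spans 11 bins of the
  0.5-Hz grid.
* **Estimator bias.** With 3 segments, `E|Im C|` under independence is
  ≈ 0.33 — visible in every worked example. Condition contrasts cancel
  it; absolute ImCoh values at this segment count should never be read
  as coupling strengths.

## SFC: cluster-based permutation test

Per channel pair, a paired t statistic compares the per-subject
stimulation and baseline connectivity. Suprathreshold edges
(uncorrected p below the cluster-forming threshold, default 0.05) are
split by t sign and grouped into connected components, where two edges
are adjacent iff they share an endpoint channel or have endpoints that
are montage neighbours (configurable to shared-endpoint only). Isolated
suprathreshold edges are discarded. Each cluster is scored by its
summed t; the null distribution of the **maximum** absolute cluster
score is built by within-subject condition-label exchange (all `2^n`
sign flips when the requested permutation count allows, which it does
for n = 8 subjects — 256 flips, enumerated exhaustively and logged;
otherwise sampled with the +1 Monte-Carlo correction). All clusters
with permutation p below α are retained, not only the maximum one: the
max-statistic enters only the null distribution, the standard
construction that lets several genuine clusters survive while
controlling the family-wise error.

Degenerate edges with identically zero paired differences are assigned
t = 0 (a 0/0 limit read as "no effect"); zero variance around a
non-zero mean is an error, since ±∞ statistics are disallowed.

Retained edges are annotated with `t / max|t|` (normalized t), and each
channel receives the sum of normalized t over its retained incident
edges — the node intensities of an SFC topography. The
hemispheric-lateralization degree is `100 × n_contra / n_total` over
channels with non-zero node sums; midline channels count in the total
but in neither hemisphere. The float is returned; displays round half
away from zero (9/13 → 69%, 4/28 → 14%).

**Calibration.** `fwerExperiment()` draws both conditions from one null
distribution (16-channel grid, 8 subjects, 200 permutations) and
measures the family-wise rejection rate over 500 datasets; the
acceptance suite requires it to lie in the binomial 95% interval around
0.05. The +1-corrected discrete p makes the test mildly conservative
(rates of 0.03–0.06 are typical across master seeds).

## Binary networks and multiscale indices

Per subject and stimulated limb, the k-th stimulation trial is paired
with the k-th baseline trial (session order), a paired t runs per pair
across the 9 trial pairs, and Benjamini–Hochberg FDR is applied over
all 1891 pairs. The step-up decision is `adjusted p ≤ q` — with the
strict inequality, a run of equal adjusted p values at exactly q would
be wrongly rejected. Surviving pairs become the 1-entries of the
subject's binary network.

Indices, all on unweighted graphs:

* **Global efficiency**: mean inverse shortest-path length over ordered
  node pairs; disconnected pairs contribute 0 (the 1/∞ limit — the
  definition is silent on disconnection, and this convention keeps the
  index in [0, 1] and monotone under edge addition).
* **Local efficiency**: mean over nodes of the global efficiency of the
  neighbour-induced subgraph (node excluded); nodes with < 2 neighbours
  contribute 0.
* **Smallworldness**: `(E_loc/E_loc^r)/(E_glo/E_glo^r)` with reference
  efficiencies averaged over 100 uniform G(n, m) random graphs with the
  same node and link counts (the plain "equivalent random graph"
  reading; degree-preserving rewiring is a stricter alternative not
  chosen). Deterministic given a seed; NaN with a warning when the
  references are too sparse for any connected neighbourhood.
* **Inter-/intra-hemispheric density**: inter-hemisphere links over
  `Ns²`; intra-hemisphere links over `Ns(Ns−1)/2` **unordered** pairs —
  the ordered reading would allow an intradensity of 2 for a complete
  hemisphere, contradicting its defined 0–1 range, so the range
  statement was taken as authoritative. Equal hemisphere sizes are
  required by the `1/Ns²` normalization; midline channels belong to
  neither set and report inter/intra degrees of 0 by convention.
* **Inter-/intra-hemispheric degree**: per-node link counts crossing,
  respectively staying within, the hemisphere; their sums are twice the
  corresponding link counts (tested as an identity).

Shortest paths come from igraph's BFS; the index formulas are
implemented here and verified exactly against an independent
brute-force path-enumeration oracle on hundreds of small random graphs,
plus hand-derived fixtures (path-4 global efficiency 13/18,
triangle-plus-pendant local efficiency 7/12).

## Group statistics

Paired limb comparisons of each index use a two-sided paired t with
t-based 95% CIs per limb. The effect size is Cohen's d_z (mean
difference over SD of differences); published effect-size columns for
this kind of table often leave the estimator undefined and are not
generally consistent with d_z at the printed p and n, so the output
labels its estimator explicitly and also reports the common-language
effect size. Normality is screened per comparison with Shapiro–Wilk;
a failing screen (p ≤ 0.05) triggers a warning and a Wilcoxon
signed-rank p reported alongside, never silently replacing the t.
Node-level comparisons (inter- and intra-degree per channel) are
BH-corrected across channels, separately per index family — pooling the
two families would couple their error budgets for no gain.

## The synthetic cohort

The generator exists because recordings of this kind are typically not
deposited. Its defaults are the emulated study conditions: 8 subjects
per group, 62 channels at 1000 Hz, 4-s trials, 9 trials per condition
per forearm (realized directly as epochs: 3 recorded repetitions × 3
4-s segments of a 12-s retention equals the 9-trial arithmetic), two
conditions, two forearms — 288 trials per group.

* **Noise**: pink (1/f) at SD 1 (µV), shaped in the frequency domain;
  white noise is available.
* **Planted couplings**: each edge is a band-limited Gaussian source
  injected into both endpoint channels, the second copy delayed by an
  integer-sample lag (12.5 ms → 12 or 13 samples at 1000 Hz, nearest
  integer; 12.5 ms is a quarter cycle at 20 Hz, near-maximal imaginary
  coherence across beta 2). Injection is **power-neutral**: within the
  coupling band, a fraction `strength` of the endpoint's noise power is
  replaced by the source (per-channel totals capped at 0.95 and
  rescaled for chained edges), so auto-spectra are unchanged, the
  planted in-band coherence approximates `strength`, and — critically —
  planting an edge does not bias the coherence of other pairs incident
  to the same channels, which additive injection does via the inflated
  denominator.
* **Volume-conduction nuisance**: zero-lag mixing entries add one
  shared broadband source across several channels; its coherency is
  real, so band ImCoh of mixed pairs stays at the unplanted level
  (verified over 100 trials in the acceptance suite).
* **Lateralization**: `lateralizedSpec()` chains
  `round(fraction × nEdges)` couplings through contralateral
  somatosensory-area channels and the rest through their mirrored
  homologues; chaining over shared endpoints makes the planted pattern
  a spatial cluster, as cluster-based retention requires. Couplings are
  defined relative to left-forearm stimulation and mirrored through the
  homologue map for right-forearm trials.
* **Determinism**: one master seed expands to per-trial substreams by a
  counter keyed on (group, subject, limb, condition, trial), so any
  subject's data can be regenerated independently of generation order.

What the generator does **not** emulate: dipolar forward models,
realistic artifact morphology, and — most consequentially — the strong
correlation between channel-pair statistics that real EEG exhibits
(global coherence level, spatial smoothness). Under the generator,
pair-level estimation noise is independent across the 1891 pairs, so at
an edge threshold of 0.05 roughly 95 chance edges appear in any
condition contrast and percolate through the neighbour-closure edge
adjacency into scalp-wide clusters. Passing tests therefore demonstrate
correct arithmetic and calibrated error control, not that real-data
topographies at full scale will look like the planted ones.

## Problem sizes and recovery-run parameters

Statistical properties are validated at sizes chosen to make the checks
sharp and quick:

* FWER calibration: 16-channel grid, 8 subjects, 200 permutations, 500
  null simulations.
* Lateralization recovery (`hlRecoveryExperiment()`): one group of 8
  subjects × 2 conditions × 9 trials = 144 trials on a balanced
  28-channel sensorimotor subset (378 pairs), with a 14-edge planted
  chain, shared-endpoint edge adjacency and a 0.005 cluster-forming
  threshold. The reduced pair count and stricter threshold follow from
  the percolation argument above: with independent pair noise at the
  full 1891-pair scale, chance edges flood every cluster and pin the
  recovered HL degree near 50 regardless of the planted fraction.
  At this scale the experiment recovers HL > 90% for a 0.9
  contralateral fraction and ~50% for 0.5.
* Type-I and power checks of the group comparisons run on index values
  or reduced-rate cohorts (250 Hz, 6–16 channels) to keep the suite
  fast; the statistics under test are size-invariant.
* The end-to-end determinism check runs the pipeline twice on a reduced
  cohort (3 subjects, 3 trials, 250 Hz) and compares report bytes; the
  full default run (2 × 288 trials, 62 channels) completes in minutes
  but is not exercised twice in the routine suite.

## Numerical and degenerate-input conventions

0-based, half-open epoch windows; x positive toward the right ear and
the flip realized as a label permutation; montage hemisphere labels
must match coordinate signs (|x| ≤ 1e−6 is midline) and left/right
counts must balance; Delaunay neighbour construction rejects duplicate
and collinear layouts, prunes edges beyond 1.5× the median edge length,
and restores a pruned channel's shortest edge so no channel is
isolated; EDF quantization is 16-bit over integer physical bounds with
round-trip error at most one step; Monte-Carlo p-values use the +1
correction, exhaustive enumerations do not; and every function touching
a random number generator takes an explicit seed and restores the
caller's RNG state.

## Known limitations

Sensor-space only (no source localization); no ICA implementation
behind the artifact hook; unweighted networks only (the binarization
discards effect magnitude); smallworldness references are G(n, m), not
degree-preserving; and the synthetic cohort's independence structure
makes full-scale topography recovery unrealistically hard, as discussed
above.
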