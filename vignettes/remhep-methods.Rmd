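---
title: "Methods: heartbeat-evoked potentials across REM microstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heartbeat-evoked potentials across REM microstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(remhep)
```

This vignette documents the models, parameter choices, numerical
conventions and limitations of `remhep`. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The measurement model

The heartbeat-evoked potential (HEP) is the average scalp EEG response
time-locked to the ECG R-peak. The package contrasts HEP amplitudes
between phasic REM, tonic REM and eyes-closed resting wakefulness
within subjects. The statistical unit is the per-subject,
per-condition average waveform over −200..+800 ms; inference is
performed across subjects with paired nonparametric statistics, so no
distributional assumptions are made about the waveforms themselves.

Two facts shape the design. First, the cardiac field artifact —
volume-conducted ECG visible at the scalp — is time-locked to the very
event the HEP is locked to, so it cannot be averaged away; at the
scalp it is attenuated to below 1% of the chest ECG but it is still
the main confound. The package therefore leaves cardiac activity out
of the ICA cleaning entirely and instead rules it out statistically
(windowed ECG contrasts, an ANCOVA with the ECG contrast as covariate,
contrast correlations, and a pointwise full-epoch ECG test). Second, a
condition difference in an event-locked average can also arise from a
difference in ongoing oscillatory background rather than from
event-locked processing; the surrogate-heartbeat analysis separates
the two.

## Microstate segmentation

4-s windows tile REM-scored epochs on a 1-s stride. A window is

* **phasic** if it contains ≥ 2 *consecutive* eye movements on the
  0.5–30 Hz band-passed EOG — each movement ≥ 100 μV from the local
  median with an above-half-peak width < 500 ms; "consecutive" means
  onsets ≤ 1 s apart, consistent with the observation that REM eye
  movements stay below about 2 Hz;
* **tonic** if every EOG deflection from the window median stays below
  25 μV;
* unlabeled otherwise (e.g. a single 60 μV deflection), and never
  selected.

A biphasic deflection is one movement, not two: sub-half-threshold
gaps up to 150 ms between opposite-polarity lobes are merged before
the amplitude and width criteria are applied. The 150 ms merge gap is
below the shortest plausible separation of distinct movements in a
burst and above the zero-crossing gap of a biphasic deflection at the
amplitudes of interest.

Selected segments must be ≥ 8 s apart *edge to edge* (the stricter of
the two readings of the spacing rule). Selection is greedy in onset
order, which maximizes the usable segment count; when a per-state cap
applies (100 segments per state in the first study protocol), the
capped subset is drawn with a seeded RNG, preserving the spacing
invariant. Manual artifact review is replaced by an automated veto:
windows whose EEG RMS exceeds 5× the recording median are dropped.
Wake segments are selected identically (eyes-closed: no
supra-threshold eye movements), preferring pre-sleep-onset wake and
falling back to later wake epochs only when fewer than 10 pre-onset
candidates exist.

The 25 μV tonic bound is applied to the band-passed EOG, for symmetry
with the eye-movement criterion; amplitudes are measured from the
window median because visual scoring has no explicit baseline.

## Cardiac analysis

R-peaks are detected fully automatically (band-pass 5–30 Hz,
differentiate, square, 150 ms moving-window integration, adaptive
threshold, 250 ms refractory period), with polarity decided by a
majority vote over candidate windows and each detection refined to the
raw-signal extremum within ±50 ms. A CSV export/import
(`write_rpeaks`/`read_rpeaks`) supports manual review where a
semi-automatic workflow is wanted.

SDNN is the sample standard deviation (n−1) of the in-scope inter-beat
intervals, where "in scope" means both endpoints lie inside selected
segments. Because 4-s chunks yield variable interval counts, a
normalized variant dividing by √n_rr is also provided; the phrase
"normalized by the available number of RR intervals" admits more than
one formula, so both variants are shipped and every output labels the
mode used. Frequency-domain HRV and RMSSD are out of scope — they are
not meaningful on discontinuous 4-s chunks.

## Preprocessing

EEG is band-pass filtered 0.5–35 Hz with a fourth-order Butterworth
applied forward and backward (zero phase, so peak latencies are
preserved). Eye-movement components are estimated by a seeded
fixed-point ICA (tanh contrast, deflation scheme) on the EEG
concatenated across all selected segments, in a PCA-reduced subspace
of 10 components: scalp background EEG is close to Gaussian, whose
rotation ICA cannot identify, while the large non-Gaussian ocular
source sits in the top principal components and converges in tens of
iterations. Components whose time course correlates with the EOG
above |r| = 0.4 are flagged; at most 4 are removed (the top ones by
correlation). Removal is subtractive — the flagged components'
back-projection is subtracted from the full continuous recording — so
with nothing flagged the data pass through bit-exactly, and cleaning
never increases the total EEG variance on the fitted span.
Near-Gaussian residual components that hit the iteration cap are kept
and reported as unconverged; an error is raised only when no component
converges at all.

## Epoching and averaging

One trial per R-peak inside a selected segment: samples
`[r − round(0.2 fs), r + round(0.8 fs))`, a half-open 1000 ms window
with the R-peak at time 0. Epochs may extend past their 4-s segment
into adjacent continuous data; artifact-flagged spans still veto.
Baseline is the per-trial, per-channel mean over −200..−50 ms —
stopping before the rising R-wave edge — and ECG epochs are treated
identically to EEG epochs (the equal treatment is a deliberate,
documented choice). Subjects with fewer than 200 artifact-free trials
in any condition are excluded; exactly 200 is kept.

## Cluster-based permutation inference

Paired t statistics are computed at every (channel, time) point of the
350–650 ms window of interest (late enough that R- and T-wave cardiac
field artifacts are unlikely). Suprathreshold samples (two-tailed
α = 0.05 critical t at df = n−1) form clusters through temporal
adjacency and spatial adjacency; a suprathreshold sample is kept only
if at least `min_neighbors = 2` of its spatial neighbours are also
suprathreshold. This pruning is one reading of the "at least two
neighbouring channels" rule; it is configurable down to 0 and the
single-channel examples in the test suite use 0. Channel adjacency
derives from 2-D 10–20 template coordinates with a distance threshold
chosen so the median neighbour count is ~4; the montage follows the
recording's labels (19 or 17 channels).

The cluster mass is the sum of member t values (t_maxsum). The null
distribution is built from per-subject random condition swaps — sign
flips of the paired difference maps, the exact permutation scheme for
paired designs — taking each permutation's maximum absolute cluster
mass; 5,000 Monte-Carlo draws by default. Cluster
p = (1 + #{null ≥ |mass|}) / (1 + n_perm); the +1 guard avoids p = 0
and a relative tolerance of 1e−9 in the comparison protects the
discrete atoms of small-n nulls from floating-point ties. Because both
signs are referred to the same max-|mass| null, the per-tail label
uses p < 0.025 by default, with raw p always reported; both
conventions are emitted since a p ≈ 0.04 cluster is a trend under one
reading and significant under the other. The permutation core
(thresholding, pruning, flood fill, null loop) is compiled C++ (Rcpp);
it is validated in the test suite against a pure-R flood-fill oracle
and an exhaustive 2^6 sign-flip enumeration.

The pointwise ECG comparison runs the same sign-flip scheme per time
point on the single ECG channel over the full −200..+800 ms epoch,
reporting uncorrected p values and a Benjamini–Hochberg FDR mask.

## ECG confound suite

For the window and channels of a significant cluster, per-subject mean
ECG amplitudes are contrasted with a paired t test, or an exact
Wilcoxon signed-rank test when Shapiro–Wilk (α = 0.05) rejects
normality of the differences (zero differences dropped, exact null for
n ≤ 25, rank-biserial effect size). The repeated-measures ANCOVA with
a two-level within-subject factor and a centred subject-level
covariate reduces algebraically to a regression of difference scores
on the centred covariate: the condition main effect is the intercept
test on F(1, n−2) — evaluated at the mean covariate — and with an
uninformative covariate it collapses exactly to the squared paired t
on F(1, n−1). The package reports its own degrees of freedom and this
mapping rather than forcing any particular printed convention.

## Surrogate-heartbeat specificity

Surrogate R-peaks preserve, per segment, the original peak count and
IBI multiset (permuted, re-anchored at a uniform random offset), so
rate and interval distribution match the original exactly while event
times decouple from true heartbeats; an IBI-resampling variant is
available behind a flag. Surrogates are drawn per participant per
replicate — the stronger null. Each of the 100 replicates re-epochs,
re-averages and re-forms clusters, recording the maximum absolute
cluster mass; only the original analysis needs a permutation p, so
replicates are cheap. The verdict passes when the original mass
exceeds the ⌈0.05·n⌉ largest surrogate masses (the five largest at
n = 100): under a purely oscillatory state difference the original is
an ordinary member of the surrogate distribution, while a genuinely
heartbeat-locked effect dominates it.

## The synthetic generator

`synthesize_recording()` emulates the features of overnight
polysomnography that the pipeline is sensitive to:

* **Cardiac rhythm**: IBIs from a normal distribution truncated to
  250–2000 ms — the simplest model matching the two reported moments
  (defaults 1000 ± 55 ms, i.e. ~60 bpm, SDNN ≈ 55 ms, inside the
  ranges typical of young sleepers).
* **ECG morphology**: QRS as a sum of narrow Gaussians with the R
  deflection dominant (1000 μV), plus a T-wave Gaussian at 300 ms
  post-R (width 60 ms) so T-wave-proximity confounds are exercisable.
  The R sample is the per-beat maximum by construction.
* **Cardiac-field leakage**: each EEG channel receives the ECG scaled
  by at most `ecg_leak_fraction` (default 0.005, below the 1% premise)
  with channel-dependent gains.
* **Background EEG**: 1/f noise at 15 μV RMS per channel plus
  band-limited 10–14 Hz and 15–28 Hz activity whose RMS is elevated in
  tonic spans (4 vs 2 μV and 3 vs 1.5 μV) — the oscillatory state
  difference the surrogate negative control relies on.
* **Eye movements**: biphasic ≥ 100 μV deflections (default 150 μV,
  250 ms) in bursts of 3 at 0.4 s spacing, confined to phasic spans,
  with frontal-EEG leakage decaying with template distance from
  Fp1/Fp2 — giving the ICA a recoverable source. EOG background noise
  is 5 μV RMS, small enough that the 25 μV tonic bound is rarely
  crossed by noise within a 4-s window.
* **Heartbeat-locked component**: a Gaussian bump (σ = 40 ms) centred
  600 ms post-R with a fronto-central topography, default amplitude
  1.5 μV in phasic REM and 0 in tonic and wake. The waveform shape is
  a modelling choice — the literature does not parameterize the HEP
  waveform — and the centre/width straddle the late latency range
  where REM HEP effects are reported.

State layout: optional eyes-closed wake epochs first, then REM in
which 20-s phasic and tonic spans alternate, separated by 12-s
unlabeled buffers that keep selected segments of different states
≥ 8 s apart. All signals are in μV; time is seconds internally and
milliseconds at API boundaries. The recording is a deterministic
function of the configuration, including the seed.

`simulate_hep_cohort()` generates the statistical unit directly —
per-subject condition averages with temporally smoothed (20 ms),
spatially correlated noise of 0.8 μV between-subject SD,
corresponding to averaging a few hundred trials of ~15 μV background —
which is what the type-I-error calibration and effect-recovery checks
of the cluster machinery need; running 200 full multichannel nights
through the pipeline would test the same code paths at orders of
magnitude more cost.

What the generator does **not** emulate: sleep spindles, K-complexes
and other NREM grapho-elements, respiration and movement artifacts,
realistic PQRST morphology beyond QRS+T, electrode drift, and
non-stationary heart-rate trends. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not
robustness to every artifact of real recordings.

## Problem sizes used by tests and the acceptance script

Chosen once, as the package's own desk-scale study conditions:

* calibration of the cluster test: cohorts of 12 subjects, 19
  channels, fs 512, 350–650 ms window, 1,000 permutations; 200 cohorts
  in the test suite, 100 in the acceptance script;
* exhaustive-oracle agreement: 6 subjects, 5 channels × 50 samples,
  5,000 Monte-Carlo draws vs the full 2^6 enumeration;
* surrogate controls: 12 subjects, ~33-minute REM recordings at fs 100
  with 40-s alternating state spans, giving ~300 trials per condition —
  the per-condition trial count of the overnight study — with 25
  surrogates per run (the full-fidelity default is 100), 10 runs per
  control in the test suite and 5 in the acceptance script;
* full pipeline run: 12 subjects, 27-minute recordings at fs 128
  including 7 minutes of pre-sleep wake, 2,000 permutations, trial
  screening at 100 (scaled with the shorter recordings; the overnight
  default stays 200).

## Known limitations

* The EDF writer emits plain EDF with one record per second and a
  single sampling rate across channels; EDF+ annotations, BDF and
  discontinuous records are out of scope (annotations travel in CSV /
  JSON sidecars).
* The wake contrast uses the same paired machinery as the REM
  contrasts — all three states come from the same subjects — so
  between-group designs are not covered.
* `min_neighbors` pruning and the per-tail significance label are
  documented interpretations of under-specified conventions; both are
  configurable and raw quantities are always reported.
* The ICA is intentionally minimal (ocular components only); muscle
  and line-noise components are not classified.
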