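---
title: "Dynamic vasomotor reactivity: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic vasomotor reactivity: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dvrkit)
```

## The problem

Cerebral blood flow is actively regulated: it buffers swings in arterial
blood pressure (autoregulation) and responds strongly to arterial CO2
tension (vasomotor reactivity). In early cognitive impairment this
CO2 reactivity appears to degrade, which makes it a candidate
*physiomarker* — a marker derived from a physiological model rather than
from imaging or psychometrics. `dvrkit` implements one such marker, the
**Dynamic Vasomotor Reactivity (DVR)** index, end to end: from raw
resting-state recordings of arterial blood pressure (ABP, mmHg), cerebral
blood flow velocity (CBFV, cm/s by transcranial Doppler) and end-tidal CO2
(ETCO2, mmHg by capnography), through a two-input dynamic model, to the
scalar index, and onward to the cohort-level statistics and voxelwise
DTI-association analyses in which such a marker is typically evaluated.

## The two-input model and the DVR index

Beat-to-beat deviations of CBFV around its baseline are modelled as the
output of a linear, causal, two-input system:

$$
v(n) \;=\; c \;+\; \sum_{m=0}^{M-1} k_p(m)\, p(n-m)
          \;+\; \sum_{m=0}^{M-1} k_c(m)\, x(n-m) \;+\; \varepsilon(n),
$$

where $p$ and $x$ are demeaned ABP and ETCO2, and $k_p$, $k_c$ are the
first-order (linear) kernels of the two branches. Each kernel is expanded
on a discrete Laguerre basis,

$$
k(m) = \sum_{j=0}^{L-1} a_j\, b_j^{(\alpha)}(m), \qquad
b_0^{(\alpha)}(m) = \sqrt{1-\alpha^2}\,\alpha^m,
$$

with the higher orders generated by the standard recursion
$b_j(m) = \alpha b_j(m-1) + b_{j-1}(m-1) - \alpha b_{j-1}(m)$. The basis
is orthonormal and exponentially decaying, so a handful of coefficients
($L$ of them per branch) represents a smooth kernel spanning tens of
seconds, and the least-squares problem stays small and well-conditioned on
a five-minute record. The expansion coefficients, plus an intercept, are
estimated by ordinary least squares on the convolved regressors; the
first $M-1$ samples are excluded as burn-in rather than zero-padded, which
avoids biased edge estimates. An optional ridge penalty (intercept
unpenalized) is available for ill-conditioned designs and is the advised
remedy when the two input channels are collinear.

The DVR index probes the fitted model, not the raw data: the model's
predicted CBFV response to a rectangular 5-s ETCO2 pulse is computed with
the ABP input held at baseline (zero deviation), and DVR is the mean of
that response over the 5-s window, divided by the pulse amplitude. For a
linear model the index is exactly amplitude-invariant, so it is reported
per mmHg of ETCO2; an optional flag normalizes it to percent of baseline
CBFV per mmHg. For a known system the index has the closed form
$\mathrm{DVR} = \frac{1}{N}\sum_{n<N}\sum_{m\le n} k_c(m)$ (`true_dvr()`),
which is the independent yardstick for every recovery test.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dt` | 1 | s | uniformization step; about one beat at rest, the conventional grid for beat-to-beat series |
| `M` | 50 | samples | kernel memory (50 s at `dt` = 1): covers slow vasomotor dynamics |
| `L` | up to 4 | – | Laguerre functions per branch; 3–4 suffice for smooth kernels |
| `alpha_grid` | 0.2–0.8 | – | kernel decay candidates for the structure search |
| `ridge` | 0 | – | least squares by default; positive values stabilize collinear designs |
| `pulse_duration_s`, `window_s` | 5, 5 | s | the probing pulse and the averaging window are tied together |
| `pulse_amplitude` | 1 | mmHg | arbitrary under linearity; per-mmHg units make indices comparable |
| `refractory_s` | 0.3 | s | minimum beat spacing in detection |
| `breath_min_sep_s` | 1.5 | s | minimum spacing of end-tidal maxima |
| `artifact_sd` | 4 | robust SDs | beat rejection threshold |
| `max_reject_frac` | 0.2 | – | above this the recording is declared unusable |

Model order, decay, memory and regularization are conventions surfaced in
`dvr_config()`; the structure search (`select_structure()`) picks
$(\alpha, L)$ per branch by validation NMSE on a *temporal* 70/30 split —
random splits would leak time-series structure — with ties broken toward
the smaller order and then the smaller decay.

## Preprocessing conventions

Raw waveforms are reduced to beat-to-beat values: beat onsets are found by
a derivative-threshold upstroke search refined to the preceding diastolic
minimum; ABP and CBFV become per-beat means over `[onset_i, onset_{i+1})`;
ETCO2 is the breath-wise end-tidal value (local capnogram maxima at least
1.5 s apart) assigned to beats by sample-and-hold, because end-tidal CO2
is physiologically a per-breath constant — interpolating it would invent
intra-breath dynamics. Artifact rejection flags beats more than 4 robust
SDs (scaled median absolute deviation) from the channel median or with
inter-beat intervals outside 0.3–2.0 s, and linearly interpolates over
them; the MAD scale is used instead of the plain SD so that heavy
contamination cannot inflate the threshold and mask itself. A recording
with more than 20% rejected beats is refused outright. The cleaned series
is linearly interpolated onto a uniform `dt` grid and each channel is
demeaned, with the means kept as baselines.

## What the synthetic generators emulate — and what they do not

The package is developed and tested against its own generators, so it is
worth being precise about what they contain.

**Hemodynamic systems and subjects** (`true_model()`,
`simulate_subject()`): ABP and ETCO2 deviations are independent Gaussian
fluctuations low-passed below 0.1 Hz with a second-order Butterworth
filter — the resting vasomotor band. An IIR filter is used deliberately:
it concentrates power at low frequencies while leaving nonzero energy
everywhere, so the inputs remain persistently exciting and noise-free
records are identifiable to machine precision. CBFV is the exact kernel
convolution plus white observation noise; `noise_frac = 0.1` scales the
noise to 10% of the clean output power. Default input scales are 3 mmHg
(ABP) and 1.5 mmHg (ETCO2) SD, ordinary resting variability.

**Raw waveforms** (`simulate_waveforms()`): a zero-mean systolic contour
repeated at constant heart rate carries the slow beat-level means, so
per-beat averages recover them exactly; the capnogram rises to a per-breath
alveolar plateau whose value is the slow ETCO2 fluctuation sampled at the
breath, and the model input is the *held end-tidal sequence* switching at
the end-tidal instants — the same quantity capnography can actually
measure, so the preprocessing chain is tested against a recoverable
ground truth. Ground-truth beat onsets and end-tidal events are returned
with the record.

**Cohorts** (`generate_cohort()`): the 11 markers/scores are drawn from a
Gaussian copula whose correlation target and per-group means/SDs default
to values emulating a published MCI-versus-control cohort (16 controls,
36 patients; see `default_marker_targets()`). Age is Normal(65, 7) years,
gender Bernoulli(0.5), education Normal(16, 2) truncated to 10–22 years,
independent of the markers. One structural consequence to note: the
correlation target is a *within-group* property of the copula, while a
pooled-sample correlation additionally reflects group-mean separation —
with the default group effects the pooled DVR–FA correlation runs a few
hundredths above the copula target. The generator cannot pin group
means/SDs and the pooled correlation simultaneously; tests therefore
check the correlation target on null-effect cohorts.

**Voxel datasets** (`generate_voxel_dataset()`): inside a designated
fraction of each toy-atlas region, the metric follows
`intercept + slope * DVR + noise` across subjects; all other voxels are
pure noise. The ground-truth association mask is returned, which is what
lets region-percentage recovery and FDR control be scored exactly.

None of these generators attempt MR physics, TBSS skeletons, heart-rate
variability, posture changes, breath-holds or other nonstationarities.
Passing tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to every artifact of
clinical recordings.

## Statistical layer

Group comparisons use the unequal-variance (Welch) t-test with
Satterthwaite degrees of freedom; the summary-statistics interface is
first-class because published group tables print only means, SDs and ns,
and recomputing a table's p-values from its printed summaries is the
natural external check of the implementation. Categorical demographics use
the Pearson chi-square without continuity correction. Covariate separation
(age, gender, education) is a pooled fixed-effects OLS: each subject's
adjusted value is their residual plus the fitted value at the
*control-group* covariate means, which leaves the control-group mean of
every adjusted variable exactly unchanged — so before/after columns of a
group table remain directly comparable. Pairwise correlations use Pearson
r with pairwise-complete deletion and the t-transform p-value; the number
of complete pairs is always reported. No multiple-testing correction is
applied across the 11 markers of a group table — raw p-values are
reported with 0.05/0.01 flags — because that is the reporting convention
of the cohort tables this layer mirrors.

## Voxelwise layer

Each masked voxel's metric values across subjects are correlated with the
per-subject DVR; zero-variance voxels are excluded rather than given
arbitrary values. Significance defaults to two-sided p < 0.05
uncorrected, with Benjamini–Hochberg FDR available by flag; the choice is
recorded in the mask's provenance attributes, and permutation/TFCE-style
corrections are out of scope. Correlations use unadjusted DVR by default
(adjusted values can be passed in instead). Region tables count
significant voxels per atlas label, report percentages of region size,
flag regions exceeding 30%, and append a whole-mask totals row. Volumes
are taken in native orientation; no registration or resampling is
performed, so inputs must be pre-aligned.

## Numerical choices

* Least squares via QR; rank deficiency with `ridge = 0` is an error that
  names the remedy rather than a silent pseudo-inverse.
* NMSE is residual power over output power on the post-burn-in window;
  0 means perfect prediction.
* CSV writers render doubles at 17 significant digits and the readers
  parse through base R's correctly-rounded converter, so waveform files
  round-trip bit-identically.
* All generator randomness flows through a single seed argument
  (`withr::with_seed`), making every synthetic object a pure function of
  its arguments.
* File writes are write-then-rename, so a crashed run never leaves a
  half-written artifact.

## Problem sizes used by the test suite

The suite exercises: 100 synthetic subjects at 5.5-minute record length
for DVR recovery (noise-free and at 10% noise power); 10,000 null-cohort
replicates for Welch type-I calibration; an 8,000-voxel null volume for
voxelwise calibration; cohorts of 10,000 per group for moment
convergence; and toy 864-voxel atlases for region tallies. These sizes
were chosen to make Monte-Carlo tolerances tight relative to the
assertions while keeping the full suite and the acceptance script
comfortable on a single CPU.

## Known limitations

* The dynamic model is strictly linear (first-order kernels); nonlinear
  extensions are a reserved extension point, not implemented.
* DVR units are a declared convention (cm/s per mmHg of pulse amplitude);
  published DVR magnitudes are printed unitless, so cross-study numeric
  comparability depends on matching conventions.
* The covariate adjustment anchors at control-group covariate means; other
  anchorings (pooled means) shift adjusted group means by a constant but
  leave test statistics unchanged.
* Exact per-test sample sizes in emulated cohorts with missing scores are
  configurable, not inferred.
* Region tables from the toy atlas demonstrate the mechanics; real
  white-matter atlas analyses additionally depend on registration and
  skeletonization steps that are explicitly out of scope.
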