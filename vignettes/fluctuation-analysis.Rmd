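---
title: "Models and methods: synaptic current fluctuation analysis and receptor mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synaptic current fluctuation analysis and receptor mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampafluct)
```

## Scope

`ampafluct` implements the quantitative machinery used to characterize
AMPA-receptor function at synapses: detection and quality control of
miniature excitatory postsynaptic currents (mEPSCs), peak-scaled
non-stationary fluctuation analysis (NSFA) yielding single-channel current
and conductance, evoked-response metrics (rectification index, KA/Glu,
AMPAR/NMDAR and paired-pulse ratios, LTP timecourse normalization), and
FRAP recovery fitting with acquisition-bleach correction.  Because real
recordings of this kind are rarely deposited, the package pairs every
analysis with a synthetic-data generator that exports its ground truth, so
each stage can be validated by parameter recovery.

## The channel-ensemble model behind NSFA

A postsynaptic current through `N` independently gated channels with
single-channel current `i` (pA, negative for inward) and open probability
`p(t)` has, at each instant,

$$\mu(t) = N\,i\,p(t), \qquad
  \sigma^2(t) = N\,i^2\,p(t)\bigl(1-p(t)\bigr) + \sigma_b^2,$$

where $\sigma_b^2$ is the background (recording-noise) variance.
Eliminating $p(t)$ gives the variance–mean parabola fitted by `nsfa()`:

$$\sigma^2(I) = iI - \frac{I^2}{N} + \sigma_b^2 .$$

The single-channel current is the initial gradient of this parabola, and
the conductance follows as $\gamma = i/(V_m - E_{rev})$ (pA/mV = nS,
reported in pS).  At the conventional potentials $V_m = -60$ mV and
$E_{rev} = 0$ mV, $i = -1.524$ pA corresponds to $\gamma = 25.4$ pS.

The generator (`gen_channel_events()`) draws the open count per sample as
Binomial(`N`, `p(t)`) with `p(t) = p_peak * w(t)` and `w(t)` the unit-peak
biexponential `exp(-t/τ_d) − exp(-t/τ_r)`.  Gating is drawn independently
per sample: NSFA uses only the pointwise mean–variance relation, so
temporal gating correlations add realism without changing the quantity
under test.  Two consequences are worth knowing:

* the simulated noise is white at the full 100 kHz bandwidth, which is
  *harsher* than a filtered physiological recording; event-kinetics
  measurements must therefore smooth before locating level crossings
  (see below), and
* passing recovery tests demonstrates correctness of the estimator under
  the model's assumptions (independent channels, homogeneous `i`,
  stationary background noise), not robustness to dendritic filtering or
  correlated channel behaviour, which the generator does not emulate.

## The analysis pipeline and its numerical choices

`nsfa()` runs: template detection → event measurement → QC → alignment →
peak scaling → decay-phase variance → binning → parabolic fit.

**Detection.**  A unit-peak biexponential template (defaults τ_rise = 0.5
ms, τ_decay = 9 ms, matching the 8–11 ms decay range of measured AMPAR
minis) is fitted at every offset as `scale * template + offset`; an event
is flagged where the detection criterion `scale / SE(scale)` exceeds the
threshold (default 4).  The effective amplitude detection limit is
`threshold × noise SD` and is reported with every run — with 2 pA noise
the default threshold detects events larger than ≈ 8 pA.  No published
numeric criterion exists for this preparation, so the default is declared,
not inferred.

**Alignment.**  Events are aligned on their point of steepest rise.  For
biexponential kinetics the steepest slope sits essentially at the onset,
so a pointwise derivative argmax under broadband noise is degenerate (its
jitter spans the whole rising phase; we measured a ~0.5 ms SD at realistic
signal-to-noise).  The package therefore anchors the steepest-rise point
at its fixed, known offset inside the best-fitting template position,
which uses the whole waveform and reduces alignment jitter to about one
sample.  Alignment jitter matters: it inflates decay-phase variance in
proportion to the squared slope of the mean waveform and was the largest
single source of conductance bias in development-scale experiments.

**Rise time.**  10–90% rise times are interpolated on a 0.1 ms-smoothed
copy of the event, taking the *first* crossing of each level before the
peak.  Anchoring 90% at its last crossing instead inflates the estimate
whenever the trace hovers near the peak (roughly twofold under the
generator's noise), which would cut most genuine events at the 0.9 ms QC
cutoff.  With first crossings the biases at the two levels are similar and
largely cancel in the difference.

**QC.**  Deterministic, logged rules replace manual curation: rise time
< 0.9 ms, exclusion of events with a neighbour within twice the template
length, removal of unmeasurable events, and a cell-level minimum of 20
surviving events for NSFA eligibility.  Rank correlations between
amplitude and rise/decay times are reported and flagged above 0.7 as an
electrical-filtering diagnostic.

**Peak scaling.**  Each event is multiplied by (ensemble-mean peak)/(event
peak), equalizing peaks so that between-event receptor-number variance
does not contaminate the gating variance.  `peak_scale()` defaults to raw
window maxima, which makes the scaled raw peaks exactly equal (and keeps
the exact-equalization invariants testable); `nsfa()` passes peaks
measured on a 0.5 ms-smoothed copy instead, because the raw maximum of a
noisy trace is biased upward by the expected maximum of the noise.

**Decay phase and binning.**  The variance analysis uses the columns from
the ensemble-mean peak to where the mean first returns to 10% of peak —
beyond that point the scale factors blow up the residual noise.  Fifteen
equal-width amplitude bins are used (equal-width, not equal-count, was
chosen; the convention is not fixed by common usage and the choice is
surfaced as a parameter).  The fit is unweighted least squares over bins;
a points-per-bin weighted variant is available behind a flag.  Because the
parabola is linear in `(i, 1/N, σ_b²)`, the unconstrained solution is
exact (machine precision on analytic bins); the physical constraints
`N > 0`, `σ_b² ≥ 0` trigger a bounded refit only when violated, and the
result is flagged.  Peak-scaled NSFA is known to bias `N`; only `i` (and
hence γ) carries recovery guarantees here, which is why the recovery suite
scores γ within 10% but N only loosely.

## Evoked-response metrics

The rectification index is $-(I_{+40}-I_0)/(I_{-60}-I_0)$; any ohmic
model with $E_{rev}=0$ gives exactly 2/3, and polyamine block of the
outward limb depresses it.  The generator's block model is a decreasing
logistic in voltage (unblocked fraction $1/(1+e^{(V-V_{1/2})/k})$,
defaults $V_{1/2}=+10$ mV, $k=20$ mV); no mechanistic block equation is
implied — the defaults were chosen so the default model rectifies in the
0.1–0.2 band typical of unedited GluA2(Q) homomers.  Amplitudes are
measured against a 5 ms pre-stimulus baseline; paired-pulse second
amplitudes are measured from the extrapolated monoexponential tail of the
first response; "response initiation" is defined as the first crossing of
3× baseline SD after a 2 ms artifact blank; the NMDAR component is read
100 ms after initiation with a 1 ms local average; LTP series are averaged
in one-minute bins and normalized to the mean of all pre-induction
amplitudes.  These window choices are stated here because no standard
fixes them; all are parameters.

## FRAP model and fitting

The bleached-region model is single-exponential recovery toward a plateau
with an immobile fraction `1 − plateau`, multiplied by a per-frame
geometric acquisition-bleach factor shared with the reference region:

$$F(t) = F_{post} + (P\,F_{pre} - F_{post})\bigl(1 - e^{-(t-t_b)/\tau}\bigr),
\qquad F_{obs}(t) = F(t)\,k_{acq}^{\,\mathrm{frame}(t)} .$$

`bleach_correct()` divides by the reference normalized to its pre-bleach
mean; for shared geometric bleaching this is exact up to a constant that
cancels at pre-bleach normalization, so correction ∘ normalization
reproduces the ideal normalized curve to machine precision in the
noiseless case.  The recovery fit excludes the bleach-onset frame
(bleaching transient), uses the initializer τ₀ = time-to-half-recovery /
ln 2, F₀ = first post-bleach frame, P = mean of the last three frames, and
flags immobile traces (plateau within 0.02 of F₀) as τ-unidentifiable
rather than fitting an arbitrary constant.  The fluorescence at 600 s is
reported both from the fitted curve and as the empirical frame value; the
empirical value is primary, since published late-recovery numbers are
frame values.  Note that with τ ≈ 200 s, a model whose *asymptote* is set
to a published 600 s value necessarily shows an ideal F(600) about 0.03
below it — a model-definition offset, not an estimation bias.

## Problem sizes and reproducibility

The recovery suites use 20 seeded replicates of 500 events per
conductance condition (≈ 1.4 min per condition on one CPU) and 20
replicates of 26-frame FRAP acquisitions; the type-I-error calibration
uses 20 000 null replicates at n = 10 per group.  These sizes put the
Monte-Carlo error of each median comfortably inside the acceptance bands
(conductance medians vary by well under 2% across seeds).  Every
stochastic path takes an explicit integer seed, replicate seeds are drawn
once from a user seed, and `run_scenario()` writes a manifest with a
configuration hash so a run directory can be regenerated and compared
byte for byte.

## Known limitations

* Independent per-sample gating: no channel kinetics, no correlated
  openings; full (non-peak-scaled) NSFA of evoked trains and open-
  probability estimation are out of scope.
* The delimited sweep format is the only storage dialect; vendor
  acquisition formats (ABF, Igor) and HDF5 containers are not read.
* One-exponential FRAP recovery only; diffusion-equation models and
  two-component recovery are not fitted.
* Peak-scaled NSFA's `N` estimate is reported but not guaranteed; treat
  it as a diagnostic.
* The mEPSC eligibility rules (0.9 ms rise cutoff, 20-event minimum,
  15 bins) are conventions of the assay, exposed in `run_config()`.
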