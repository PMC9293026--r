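---
title: "Methods: automated low-density ERP analysis and its reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated low-density ERP analysis and its reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpreliab)
```

`erpreliab` implements an automated analysis chain for visual
event-related potentials (ERPs) recorded from an 8-channel montage in
toddlers, together with the psychometrics needed to judge whether the
extracted features are stable enough to serve as individual-difference
measures. This vignette explains the model and procedure, every tunable
parameter that matters, what the synthetic-data generator does and does
not emulate, the numerical choices, and the known limitations.

## The measurement model

Three components are measured. Checkerboard trials elicit the occipital
P1, extracted at Oz as the most positive peak between 50 and 200 ms
after stimulus onset. Face trials (upright and inverted) elicit the
N290 — most negative peak between 190 and 350 ms — and the P400 —
300–500 ms — both measured at the average of P7 and P8. The P400's broad
morphology makes single-peak identification unreliable, so only its mean
amplitude is extracted; for P1 and N290 the peak latency and a 60-ms
windowed peak amplitude are extracted, and for the N290 additionally the
190–350 ms mean amplitude. Peak amplitudes are means over
latency ± 30 ms rather than single-sample values because noise is
maximal at the peak sample itself.

## Preprocessing

Epochs run from −100 to 600 ms around each onset (351 samples at
500 Hz). The fixed pipeline order is: segment → band-pass → DFT line
filter → crop → baseline-correct → flag artifacts → exclude bad
channels → per-family trial rules → re-reference.

* **Band-pass 0.1–40 Hz.** Realised as a 4th-order Butterworth band-pass
  applied forward and backward (zero phase), so peak latencies are not
  displaced; the effective magnitude response is the squared single-pass
  response, exposed by `bandpass_response()` so tests can compare
  measured against designed attenuation. Each epoch is filtered with 3 s
  of real recording context on both sides (reflection-padded only at the
  recording edges, and logged); transients live in the padding and are
  cropped away.
* **DFT line filter at 50/100/150 Hz.** Sine and cosine regressors at
  each frequency are fit by least squares over the padded segment and
  subtracted. Over an integer number of cycles this cancels a line
  component exactly (to numerical precision) and leaves orthogonal
  frequencies untouched, which the tests assert at the 1e-6 µV level.
* **Baseline** is the −100..0 ms mean, subtracted per channel; averages
  are re-baselined after trial averaging.
* **Artifact flags.** A channel within a trial is flagged *flat* when its
  maximum absolute amplitude over the epoch does not exceed 0.0001 µV,
  and *amplitude* when any sample strictly exceeds ±150 µV. "Exceeds" is
  read strictly on both rules: a sample at exactly 150 µV is retained,
  and the boundary behaviour is pinned by tests.
* **Channel exclusion** removes a channel flagged on 80 % of the
  family's trials or more (inclusive), assessed after filtering and
  before trial exclusion — the source procedure does not state the
  ordering, and this choice keeps channel badness a property of the
  filtered data actually analysed.
* **Trial rules and re-referencing.** Checkerboard trials are excluded
  when Oz is flagged; face trials when P7 and/or P8 is. Surviving trials
  are re-referenced trial-wise: to Cz when Cz is clean, else to
  mean(C3, C4) when both are clean, else the trial is dropped
  (`no_reference`). Flags are computed once, on the pre-re-reference
  signal, since flagging precedes re-referencing in the procedure.

## Peak identification

The sample-wise scan marks an interior sample as a positive peak when it
strictly exceeds both neighbours. When two consecutive samples are equal
and the next one falls, the *second* equal sample is the peak; when the
next one rises, the run is part of a rising plateau and is skipped.
Runs longer than two equal samples generalise the same way: the run is
one candidate whose peak is its last sample, provided the run is bounded
by lower values on both sides (the two-sample rule only specifies the
pair case; this is the natural extension and is pinned against a
brute-force oracle over all length-6 sequences on {−1, 0, 1}).
Negative peaks mirror the logic; endpoints are never peaks.

Component selection keeps same-polarity peaks inside the component
window; with several candidates the largest amplitude *in the polarity
direction* wins (the source is silent on absolute-versus-directional;
directional is chosen), ties resolved by the earlier latency for
determinism. If no candidate exists the window widens by 20 ms per side
(e.g. P1: 30–220 ms) and the search repeats; failure marks the feature
invalid and it propagates as missing. A selected peak must also beat, in
point amplitude, the largest same-polarity peak in the baseline window —
point amplitudes, not 60-ms means, so the comparison never averages
across the baseline/stimulus boundary.

## DTW direction

For a peak-free latency measure, the individual average and the grand
average are cropped to the component window (P1 window for
checkerboards, N290 window for faces) and aligned by dynamic time
warping with local cost `|ref[i] − ind[j]|` (squared difference
available as `dtw.metric = "sq"`), steps (1,1), (0,1), (1,0), and
boundary-to-boundary alignment. The statistic is the signed area between
the warping path and the main diagonal, normalised by the area under the
diagonal: `sum(j − i) / (N(N−1)/2)` over path vertices. Ties in the
dynamic program prefer the diagonal step, then the step advancing the
individual index; this makes the self-alignment path unique so that
direction(x, x) = 0 holds exactly, and a delayed waveform warps to
positive direction (longer latency), an advanced one to negative. No
global band constraint is applied — windowing by cropping already
restricts the comparison. Exhaustive path enumeration on short segments
serves as the oracle for the dynamic program in the tests.

## Reliability statistics

ICC(3,1) — two-way fixed effects, single measures, consistency — is
computed from the subjects × sessions ANOVA mean squares:
`(MS_R − MS_E) / (MS_R + (k − 1) MS_E)`, k = 2. Confidence intervals and
p-values use the F statistic MS_R/MS_E with (n−1, (n−1)(k−1)) degrees of
freedom; the p-value is one-tailed (H1: ICC > 0), a choice documented
here because the source does not state sidedness. Negative estimates are
reported as computed, never truncated. Band edges are implemented as
poor < .40 ≤ fair < .60 ≤ good ≤ .75 < excellent, reproducing the
stated labels at their quoted edges (the interval (.59, .60) and the
point .75 are otherwise ambiguous). Rows with missing values are dropped
pairwise per cell and the retained n reported per cell.

Test–retest tables pair session 1 and session 2 features per
(condition set, feature, trial count). Split-half internal consistency
draws n clean trials at random, alternates them in draw order into
halves A and B, extracts features from each half-average, and computes
ICC(3,1) between halves within a session. The inversion effect is the
upright − inverted difference per measure; its group-level test is a
paired t on subjects with at least 20 clean trials per orientation.

Subsampling draws are independent across trial counts (not nested); the
source is silent on nesting, and independence keeps each cell an honest
random draw. Every draw's seed derives from the master seed by a
documented rolling hash over (subject, session, condition set, n, stage)
and is logged, so any table cell can be reproduced in isolation.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground-truth
oracle. Components are Gaussian bumps — the procedure under test assumes
smooth unimodal peaks, and a Gaussian gives closed-form truth for
latency, point and windowed amplitudes. Defaults place P1 at
120 ± (10 between, 6 within) ms, 12 ± (3, 1.5) µV at Oz; N290 at
280 ± (12, 8) ms, −8 ± (2.5, 1.5) µV and P400 at 420 ± (15, 10) ms,
+7 ± (2.5, 1.5) µV at P7/P8 — centred in their analysis windows with
dispersions keeping typical draws inside them, and magnitudes in the
range seen in toddler recordings. Per-subject means (between-SD) and
per-session deviations (within-SD) make the true ICC of each feature
analytic: `sd_between² / (sd_between² + sd_within²)`. Trial budgets
default to 72 checkerboard and 72 + 72 upright/inverted face trials per
session, two sessions per subject, stimulus onsets 1.4 s apart.

Background noise is spectrally shaped 1/f (exponent 1 by default) plus a
white floor at a quarter of its SD, at 8 µV by default. A deterministic
*common-mode* background (two sinusoids shared by all channels,
per-session phases, 15 µV) represents reference-electrode activity: it
is cancelled exactly by re-referencing — which is the physical point of
re-referencing — and it keeps Cz/C3/C4 alive in noiseless simulations,
where otherwise the flat-channel rule would flag the references and no
trial could be re-referenced at all. High-amplitude artifacts are ±250 µV
pulses injected per trial × channel at a configurable rate; flat channels
zero a whole session's channel; both are logged so tests can assert that
the flagged set equals the injected set exactly. Gaze streams run at
60 Hz with alternating geometric valid/gap runs around a target gap
fraction.

What the generator does *not* emulate: realistic scalp topography and
volume conduction, blink/EMG waveform shapes (artifacts are square
pulses), habituation across repeated faces, condition effects
(upright and inverted faces share parameters by default), and drifting
electrode impedance. Passing tests therefore demonstrate correctness of
the analysis chain under its stated assumptions, not robustness to every
physiological artifact class.

## Numerical choices and verification scales

Milliseconds map to samples by rounding to the nearest sample (ties half
up); window endpoints are inclusive after rounding. The 60-ms peak
window is clipped at epoch edges. Event times convert to samples as
`round(t · fs)`. EDF output is 16-bit with per-channel symmetric
physical ranges, so round-trips are exact to half a quantisation step
(about 0.01 µV at ±400 µV); the EDF codec is cross-checked against an
independent reader. Gap durations compare with a 1 ns tolerance because
eye-tracker time stamps are floats.

Two verification subtleties are worth recording. First, an epoch's
filtered content is not exactly the filtered kernel: the 0.1 Hz
high-pass leaves a small undershoot (≈ 0.02–0.08 µV here) that spreads
over seconds, so neighbouring trials 1.4 s away deposit a visible floor
in each epoch — a property of the published filter on continuous
recordings, not an implementation artifact. Second, because the N290 and
P400 overlap, a subject with a weak N290 can have a 60-ms windowed
amplitude arbitrarily close to zero, at which point *relative* error
against that truth is ill-posed. Feature-recovery checks therefore run
the noiseless cohort at the component mean parameters (dispersion SDs
zeroed), where truth targets are well-scaled; recovery there is within
one sample in latency and two percent in windowed amplitude across every
trial-count grid. Dispersion remains active in all reliability checks,
which is where it belongs.

Verification problem sizes are chosen for a thorough but quick suite:
feature recovery uses 3 subjects × 2 sessions at the full trial budget;
split-half logic uses 12-subject pure-signal and 16-subject pure-noise
cohorts; ICC recovery uses the latent score layer directly (50
replicates at n = 200 per true ICC in {0.2, 0.5, 0.8}; 500 replicates at
n = 30 for CI coverage) — the estimator, not the EEG chain, is what
those replications exercise.

## Limitations

The pipeline is specific to the 8-channel montage and the three
components; windows are configuration, not re-derived from the data.
ICC variants beyond (3,1), Spearman–Brown corrections and Bland–Altman
analyses are out of scope. The DTW statistic requires a clear waveform
morphology; with weak or absent peaks it degrades like any
latency measure. EDF support covers plain 16-bit EDF, not EDF+
annotations or vendor-native formats.
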