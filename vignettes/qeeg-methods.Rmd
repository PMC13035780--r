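---
title: "Methods: quantitative EEG biomarkers for two-timepoint stroke studies"
author: "qeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG biomarkers for two-timepoint stroke studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

After an ischemic stroke, cortical dysfunction shows up in the resting EEG
as a shift of spectral mass toward slow rhythms (delta, theta) at the
expense of the fast rhythms (alpha, beta) that accompany normal cortical
function, and as a loss of signal complexity: the EEG becomes more regular
and more predictable. `qeeg` implements the standard quantitative pipeline
for a two-group (treated vs. control), two-timepoint (baseline T0,
post-treatment T1) clinical design:

1. **Preprocessing** (`preprocessRecording`): zero-phase Butterworth
   bandpass 1–45 Hz, common average reference, and selection of five 4-s
   artifact-free epochs (20 s of analyzable signal).
2. **Spectral features** (`computeFeatures`): relative power spectral
   density (rPSD) in delta 1–4, theta 4–8, alpha 8–13 and beta 13–30 Hz,
   from Welch's method (1-s Hann windows, 50% overlap), normalized by the
   total 1–30 Hz power.
3. **Nonlinear features**: Lempel–Ziv complexity of the median-binarized
   signal, normalized as `c(n)·log2(n)/n` (LZ76 exhaustive-history
   parsing), and approximate entropy (Pincus; `m = 2`, `r = 0.2·SD`,
   Chebyshev distance, self-matches included).
4. **Hemisphere summary** (`hemisphereFeatures`): features of the three
   affected-side electrodes (C3/P3/O1 for left infarcts, C4/P4/O2 for
   right; 10–20 convention, odd = left), per electrode and as the
   across-region mean.
5. **Statistics** (`analyzeCohort`): paired t within groups (T0 vs. T1),
   pooled-variance independent t between groups at T1, chi-square for
   categorical baseline comparability, Pearson correlation of T1 features
   with the NIHSS improvement `ΔNIHSS = NIHSS(T0) − NIHSS(T1)`, and
   Benjamini–Hochberg FDR within contrast families. All tests are
   two-sided at α = 0.05.

Because clinical EEG recordings are private, the package ships a
first-class synthetic-cohort generator (`synthCohort`) whose defaults
encode the study conditions the pipeline targets, so every stage is
testable end to end.

## Feature definitions and conventions

**Welch rPSD.** Each 4-s epoch contributes seven 1-s mean-detrended,
Hann-tapered, 50%-overlapping segments; periodograms are averaged across
all segments of all five epochs, and band power is integrated once from
the averaged PSD. The estimator satisfies the discrete Parseval identity
(`sum(psd)·df` equals the mean detrended segment variance). The Hann taper
is the default for its sidelobe roll-off; Hamming and boxcar are
selectable.

**Band-edge convention.** The four bands share edges at 4, 8 and 13 Hz and
tile [1, 30] Hz. With 1-Hz Welch resolution, each PSD bin represents a
1-Hz-wide interval centred on its frequency, and a bin lying on a shared
edge is split pro rata between the two bands (`bandRpsd`). This
interval-apportioned rectangle rule has two properties a whole-bin
assignment lacks: no energy is double counted or systematically shifted by
half a bin, and for a flat spectrum the band fractions equal the exact
bandwidth ratios 3/29, 4/29, 5/29, 17/29. The four fractions always sum
to 1.

**LZC.** The signal is binarized at its median (robust to outliers and
invariant under monotone amplitude transforms; mean thresholding is
selectable), parsed by the LZ76 scan-and-copy rule, and normalized by
`n/log2(n)`, which drives the fair-coin expectation to 1. Both the
normalized value and the raw phrase count are returned. A constant signal
binarizes to the all-zeros sequence with a degenerate-input warning.

**ApEn.** `Φ^m(r) − Φ^(m+1)(r)` with natural logarithms, self-matches
included, tolerance `r = 0.2·sd(x)` (so the measure is scale invariant)
and Chebyshev template distance. A constant series returns 0 with a
warning. Both complexity measures are computed per epoch and averaged
across the five epochs rather than on the concatenated 20 s: concatenation
would create artificial discontinuities at epoch joins that inflate both
measures.

**Epoch selection.** The manual artifact screening of clinical practice is
replaced by a deterministic rule: non-overlapping 4-s candidate windows
from t = 0, rejection when any channel's peak-to-peak amplitude exceeds
200 µV, first five survivors kept. The rule is reproducible and testable;
recordings cleaned by external tools (e.g. ICA) can simply be supplied as
input.

**Statistical families.** FDR correction is applied within one family per
contrast type, separately for the two within-group families and the
between-group-at-T1 family; whether within- and between-group p-values
should be pooled into one family is genuinely underdetermined, and
separate families are the more conservative reading for the between-group
claims. Clinical NIHSS tests and baseline-comparability tests are reported
uncorrected (`q_fdr = NA`): they are single planned comparisons, not part
of the multi-feature EEG screen. Correlations are reported with raw
p-values.

A note on interpretation: an *increase* of ApEn is read here, per the
standard Pincus semantics, as *less* predictable (more complex) dynamics —
recovering cortex moves away from pathologically regular slow-wave
patterns, so complexity and entropy rise together with clinical
improvement.

## The synthetic cohort

`synthSignal` builds one channel as a sum over the four bands of
band-limited Gaussian noise (constructed in the frequency domain, so the
placed band variances are exact by Parseval) plus a fixed sinusoid per
band (2.5, 6, 10, 21.5 Hz). A single knob, `complexityLevel` ∈ [0, 1],
sets the noise share of every band's variance: 1 is pure broadband noise
(maximal LZC/ApEn), 0 is a pure tone mixture (quasi-periodic, minimal
complexity), and the band-power composition is unchanged along the way.
Per-band tones — rather than a single alpha tone — are what make the
complexity knob orthogonal to the band fractions.

`synthCohort` draws, for each subject and session, affected- and
healthy-hemisphere band-fraction targets from Dirichlet distributions
around the group-level targets, synthesizes the six 10–20 channels
(affected triple vs. healthy triple), and generates NIHSS scores with the
improvement linearly linked to the subject's realized T1
affected-hemisphere alpha/beta ratio plus Gaussian noise, rounded to
integers and clipped so `NIHSS(T1) ≥ 0`. Baseline NIHSS is uniform on
5–20 (the inclusion window), age uniform on 40–80, sex and infarct side
balanced Bernoulli. One master seed drives everything; per-subject streams
are derived arithmetically, so enlarging a cohort never reshuffles
existing subjects.

### Calibration defaults (the emulated study conditions)

| Parameter | Default | Source/rationale |
|---|---|---|
| subjects per group | 40 | study design |
| sampling rate | 1000 Hz | acquisition setting |
| analyzable duration | 20 s | five 4-s epochs |
| amplitude | 20 µV RMS | typical resting EEG |
| affected fractions, treated T0 | (45.9, 24.9, 18.0, 11.2)% | printed group means, normalized to the simplex |
| affected fractions, treated T1 | (35.9, 21.5, 24.2, 18.4)% | printed group means, normalized |
| affected fractions, control (both timepoints) | (44.6, 24.7, 18.6, 12.1)% | control baseline row, normalized |
| healthy-hemisphere fractions | control baseline values | reported as unchanged; explicit assumption |
| Dirichlet concentration | 60 | moment-matches the printed between-subject SDs (≈4–6 points) |
| complexity level | treated 0.6 → 0.9; control 0.6 → 0.6 | reproduces the reported complexity ordering |
| ΔNIHSS model, treated | `7.2 + 2.55·(ratio − ref) + N(0, 1.63)` | mean 7.2 ± 2.1 with Pearson r = 0.632 against the alpha/beta ratio |
| ΔNIHSS model, control | `4.5 + 1.37·(ratio − ref) + N(0, 1.5)` | mean 4.5 ± 1.8; no correlation is reported for controls |

Two deliberate departures from the printed group tables are encoded here.
First, the printed control-group T1 rows (beta 11.6 → 16.8%, LZC
0.40 → 0.44) are irreconcilable with the same report's inferential
statement that the control group showed *no* significant changes: at the
printed dispersions and n = 40, a paired t on those shifts is unambiguously
significant. The generator follows the inferential result — control T1
targets equal control T0 targets — because the qualitative finding, not
the cell values, is what the pipeline's validation reproduces. Second,
printed band-power rows do not sum to 100% (96.0–101.2%); each row is
normalized onto the simplex, moving individual cells by at most ±0.5
percentage points.

### Why the generator pre-distorts band variances

A 1-s Welch window smears spectral energy by roughly ±1 Hz, and the
1–45 Hz Butterworth bandpass attenuates the bottom of the delta band. For
a delta-heavy spectrum with a hard cutoff at 1 Hz this is not a cosmetic
effect: the analysis chain attributes only ≈78% of boxcar delta-band power
back to delta (the rest leaks below 1 Hz, into theta, or is absorbed by
the filter), so naively placed variances would come back 5–8 percentage
points off. The generator therefore measures the chain's band-attribution
response once — by probing the package's own bandpass + Welch + band
integration path with sinusoidal lines (`bandTransfer`; averaging two probe
phases gives the uniform-phase expectation exactly, since the chain is
linear in the signal) — and solves the resulting linear system so that the
*expected analyzed* fractions equal the targets (`compensateFractions`).
The probe grid is 0.1 Hz; matrices are cached per configuration.

The average reference couples channels: with six channels, ≈10% of each
hemisphere triple's analyzed noise power originates in the other triple.
For independent noise this mixing is linear in power and is inverted
jointly with the Welch compensation (an 8 × 8 system,
`jointCompensate`). The per-band tones are handled differently: coherent
sinusoids do not mix in power, and subtracting the channel mean of
randomly phased tones would inject large interference variance. The
generator instead assigns the three channels of each hemisphere tone
phases 0, 2π/3 and 4π/3; their sum is identically zero, so the average
reference passes every tone through exactly unchanged, deterministically.

### What the generator does and does not emulate

It reproduces the statistical structure the pipeline assumes: band-power
composition and its between-subject dispersion, a monotone complexity
knob, hemisphere asymmetry, the NIHSS linkage, and the group × time
design. It does **not** emulate 1/f spectral shape, physiological
artifacts (blinks, EMG — only optional amplitude spikes for testing the
rejection rule), volume conduction, within-subject T0–T1 correlation
(sessions are drawn independently, making paired tests conservative), or
realistic absolute complexity magnitudes: at 1000 Hz a band-limited signal
is heavily oversampled, so binarized runs are long and absolute LZC/ApEn
values sit well below those of clinical tables, while their ordering and
monotonicity are preserved. Passing recovery tests therefore validates the
pipeline's internal consistency, not its behaviour on real patient data.

## Numerical choices and degenerate inputs

* Butterworth order 4 (per edge), applied forward–backward: zero phase
  distortion protects the complexity measures; the effective attenuation
  doubles in dB. Implemented as a compiled direct-form-II-transposed loop
  with the same zero-padding convention as `signal::filtfilt` (equivalence
  is asserted in the tests).
* Candidate epochs start at t = 0 and do not overlap — the simplest
  deterministic placement; segment choice is otherwise unspecified in
  clinical practice.
* Welch detrending removes each segment's mean before tapering.
* Degenerate inputs error loudly rather than return numbers: zero-variance
  paired differences, equal constant groups, zero contingency marginals,
  zero-variance correlates. Constant signals in `binarize`/`apen` return
  the documented conventions (all-zeros sequence; ApEn 0) with warnings.
  Inside `analyzeCohort` degenerate cells become `NA` rows so one broken
  feature cannot abort a whole battery.
* EDF output quantizes to 16 bits over each channel's data range; the
  writer digitizes against the header-representable physical range, so a
  round trip is exact to within one quantization step.

## Simulation-study problem sizes

The validation suite runs, by design, at these sizes: exhaustive LZ76
oracle equivalence over all 8190 binary strings up to length 12; ApEn
oracle equivalence on 50 series of N = 100; spectral-limit checks over 20
seeds of 20-s signals; target recovery on four full cohorts (40 per
group); the qualitative result pattern on 20 replicate cohorts;
correlation recovery on 20 replicates; and type-I calibration on 120 null
cohorts of 15 per group (both groups generated from the control
specification), with the binomial tolerance `0.05 + 2·SE` evaluated at the
realized number of q-values. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping the default test
run fast.

## Known limitations

* Only the six analysis electrodes are required; full 32-channel montages
  are read but the average reference then differs from a dense-montage
  reference.
* The alpha/beta ratio is the only feature causally linked to ΔNIHSS in
  the generator; correlations of LZC/ApEn with ΔNIHSS arise indirectly
  and are reported but not calibrated.
* EDF support covers continuous 16-bit recordings without annotation
  channels; BDF and vendor formats are out of scope.
* No ICA or bad-channel interpolation: the amplitude threshold is a
  deliberate, testable stand-in, and pre-cleaned data can be supplied.
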