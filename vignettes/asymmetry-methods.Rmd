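---
title: "Methods: interhemispheric asymmetry of motor-imagery fNIRS responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interhemispheric asymmetry of motor-imagery fNIRS responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsasym)
```

## The problem

After a unilateral stroke, the normally contralateral-dominant pattern of
sensorimotor activation reorganizes, and the degree and direction of
interhemispheric asymmetry is a candidate marker of that reorganization.
Functional near-infrared spectroscopy (fNIRS) recorded during motor-imagery
brain-computer-interface (BCI) training provides a response amplitude per
channel, task and session over a multi-day course — but unlike most
EEG/fMRI activation measures, fNIRS response amplitudes are *signed*:
oxyhemoglobin (HbO) responses are typically positive and deoxyhemoglobin
(HbR) responses negative, and either can invert. Classical laterality
indices assume positive inputs and misbehave on signed data. This package
implements an analysis chain whose core is a pair of bounded,
polarity-preserving asymmetry indices.

## Response estimation

Raw dual-wavelength intensities are converted to relative HbO/HbR
concentration changes by the modified Beer-Lambert law (MBLL):
`dOD = -log10(I/I0)` per wavelength, then the inverse of the
pathlength-weighted extinction system. The defaults (a standard published
extinction table for 760/850 nm, DPF 6.0, 3 cm separation) are
overridable; since both indices are scale-free ratios of GLM coefficients
from the same channel pair or task pair, the absolute MBLL calibration
cancels, which is why leaving these constants at field-standard values is
safe. The baseline `I0` is the whole-recording mean per channel: the
subsequent 0.005 Hz high-pass removes the arbitrary offset this choice
leaves behind.

Concentrations are filtered with a zero-phase Chebyshev type I band-pass,
0.005-0.09 Hz, order 4, 0.1 dB passband ripple, applied forward-backward.
Unqualified "Chebyshev" conventionally means type I, and the order is
counted before the forward-backward doubling; both conventions are
explicit in `filter_spec()`.

Response amplitudes come from an ordinary-least-squares GLM per session,
channel and chromophore. Regressors are boxcars over the 15 s (clinical)
or 20 s (healthy) motor-imagery execution windows, one per hand, plus a
single shared delta-train over all non-preparatory visual cue onsets, all
convolved with the canonical double-gamma HRF (peak delay 6 s, undershoot
delay 16 s, unit dispersions, peak:undershoot 6, 32 s kernel, unit-sum
normalization) sampled at 1/fs. Rest is left unmodeled and serves as the
GLM baseline. A preparation regressor is constructed and its
post-convolution correlation with the cue regressor reported, but it is
excluded from the fit: at 2-3 s duration it is nearly collinear with the
cue train. Two further choices deserve note:

* **Both sides filtered.** The design columns are band-pass filtered with
  exactly the same filter as the data. Filtering only the data would
  attenuate the regressors' out-of-band content asymmetrically and bias
  the coefficients; with matched filtering, noise-free recovery of
  planted amplitudes is exact up to numerical precision (asserted in the
  tests).
* **Plain OLS, no prewhitening.** No AR correction is applied; the
  reported per-coefficient standard errors therefore assume white
  residuals and understate the sampling variability of coefficients under
  the heavily band-limited noise. The group statistics never use those
  standard errors — they operate on the coefficients themselves across
  subjects and sessions — so this limitation does not propagate.

## The asymmetry indices

For signed amplitudes `a` (contralateral) and `b` (ipsilateral), both
indices use the same normalization:

    index(a, b) = (a - b) / sqrt(2 (a^2 + b^2))

The **laterality coefficient (LC)** applies it to one task's responses on
the two channels of a homotopic pair; the **task response asymmetry
coefficient (TRAC)** applies it to one channel's responses to the two
tasks. The denominator is the Euclidean norm of the response pair scaled
so the bound is exactly 1: the index lies in [-1, 1] for all finite
inputs, reaches the bound exactly when `b = -a != 0`, is antisymmetric,
and flips sign under joint negation. When both responses are zero the
index is defined as 0. No coefficient zeroing is needed and polarity is
preserved.

Three legacy laterality normalizations are reconstructed for comparison —
`(|a|-|b|)/(|a|+|b|)` (polarity-blind), `(a-b)/(|a|+|b|)` (saturates at
±1 whenever the signs differ), `(a-b)/(a+b)` (unbounded, singular at
`b = -a`) — together with the negative-coefficient-zeroing workaround.
The exact constants of the original formulas are not printed in the
source literature; these are the simplest standard forms reproducing each
documented failure mode, are labeled "reconstructed" in outputs, and are
compared via `stability_report()` (fractions at ±1 and above 0.99, 95th
percentile and maximum of |value|, overflow counts). Singular
denominators yield an overflow-flagged `Inf` sentinel, never an error.

## Lesion-referenced frame

For patients, homotopic channel values of right-lesioned subjects are
swapped so that left-side channel labels always denote the lesioned
hemisphere, and task labels become affected/intact; the operation is an
involution and never alters magnitudes. Healthy subjects stay in
left/right coordinates. Channels outside any symmetric pair cannot be
mirrored and are dropped (with a warning) from paired analyses of
right-lesioned subjects.

## Group statistics

Session-averaged values go into a repeated-measures nonparametric
factorial ANOVA by the aligned rank transform (ART): per effect, strip
the other effects via the cell-mean decomposition, rank the aligned
values with average ties, run a standard factorial ANOVA on the ranks,
and keep that effect's row. Factors are hand x channel pair for LC and
hemisphere x channel pair for TRAC, per chromophore. Two properties
matter in practice: alignment makes each effect's test insensitive to the
other effects (asserted exactly on noise-free toy tables), and because
alignment uses raw-data cell means, the procedure is invariant under
positive affine transforms of the data but *not* under general monotone
transforms — a common misconception worth stating.

The subject enters the rank ANOVA as a blocking factor by default (the
proper repeated-measures layout); `include_subject_term = FALSE` gives
the plain two-factor layout whose residual degrees of freedom
(`subjects x 2 x 14` data: 392) some published analyses report for this
design, and is exposed as a compatibility switch (`--no-subject-term` in
the CLI).

Per homotopic pair, the two conditions are compared with the two-sided
Wilcoxon signed-rank test (zeros dropped and counted; exact distribution
for n <= 25 without ties, normal approximation with continuity correction
otherwise), adjusted across pairs with the Benjamini-Yekutieli procedure,
which controls FDR under arbitrary dependence — appropriate since
neighboring channel pairs are spatially correlated. Adjustment families
are one per index kind x chromophore.

Daily dynamics: values are averaged per subject, channel and day, then an
OLS regression of value on day number is fitted per channel (pooled
across subjects at the group level, or per subject for individual
trajectories), with BY adjustment across channels within each family.
Constant series report slope 0 with p = 1 rather than an unstable t-test.
Pearson correlations link subject-level index means and slopes to
baseline ARAT and relative ARAT improvement; zero-variance metrics are
reported as missing with a flag.

## The synthetic cohort generator

Every downstream stage is validated against a generator with known ground
truth. A subject's scenario plants a GLM coefficient per channel x task x
chromophore; a session's concentration series is the HRF-convolved design
times those coefficients plus noise, so the planted values are exactly
the quantities the GLM estimates. Defaults emulate the clinical protocol:
17 s rest + 17 s motor-imagery trials (2 s preparation + 15 s execution),
4 trials per block with 2 per hand in random order, 4 or 6 blocks per
session, 1-2 sessions/day over 7-15 days capped at 24 sessions, 15.6 Hz,
the 28-channel montage; and the healthy protocol: 3 s + 20 s phases,
3 blocks, one session/day, 3.9 Hz, the 33-channel montage. For a
15-patient cohort the lesion sides and ARAT scores are the study's
printed per-patient values (8 left, 7 right).

Planted amplitudes: contralateral-task HbO amplitude 1 (arbitrary
concentration unit); the ipsilateral/contralateral ratio is solved in
closed form (`amplitude_ratio()`) so the analytic TRAC of
lesioned-hemisphere channels is +0.2 and of intact-hemisphere channels
-0.05; HbR is -1/3 of HbO, giving the inverted HbR pattern. Validation
asserts the sign pattern and ordering, not these magnitudes. "Recovering"
subjects add a daily drift of -0.05/day to the affected-hand amplitude on
all channels, which drives lesioned-hemisphere TRAC down and
intact-hemisphere TRAC up — a single mechanism consistent with declining
compensatory recruitment.

Noise is white Gaussian noise + random-walk drift + three fixed-frequency
sinusoids with random per-channel phases (Mayer ~0.1 Hz, respiration
~0.25 Hz, cardiac ~1.1 Hz; the cardiac line aliases at 3.9 Hz exactly as
in real acquisition, since components are sampled from continuous time
with no anti-alias filter). All components except part of the Mayer wave
lie outside the analysis passband. The default amplitudes are expressed
relative to the unit planted response and the white-noise level is
calibrated so that the task coefficient's sampling SD over replicate
sessions is about 0.1 of a unit amplitude under the default 4-block
clinical session — the signal-to-noise regime the validation suite
assumes.

What the generator does **not** emulate: motion artifacts, superficial
(scalp) hemodynamics, spatially correlated noise across channels,
subject-specific HRF shape, and nonstationary noise. Passing tests
therefore demonstrate correctness of the estimation and statistics
pipeline under the stated noise model, not robustness to every real-data
artifact.

## Numerical choices

* **Filter realization.** The band-pass is designed in zero-pole-gain
  form (closed-form Chebyshev prototype poles, low-pass-to-band-pass
  transform, bilinear transform with pre-warped edges) and applied as a
  cascade of second-order sections. At this band the normalized low edge
  is 6.4e-4 of Nyquist; the expanded 8th-order transfer-function
  polynomial is numerically unstable there (poles stray outside the unit
  circle in double precision), while the section cascade is exact. Tests
  assert the realized response against the analytically evaluated
  transfer function.
* **Edge handling.** Odd-reflection padding of one low-cutoff period
  (capped at series length minus one) plus steady-state initialization of
  each section, so constants map exactly through the filter's zero DC
  gain and startup transients are suppressed without excessive padding.
* **Determinism.** All synthetic randomness derives from explicit integer
  seeds via a counter-seeded generator, so identical seeds give
  bit-identical recordings and pipeline outputs, and package functions
  never perturb the caller's RNG state.
* **Degenerate inputs.** Zero-response index pairs return 0; singular
  legacy denominators return flagged sentinels; all-zero Wilcoxon
  differences return p = 1 with a flag; constant regression series return
  slope 0, p = 1; zero-variance correlation metrics return NA with a
  flag.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to exercise every
code path while keeping the default run fast: noise-free and 200-replicate
noisy recovery on single 4-block clinical sessions; ART ANOVA type-I
calibration on 1000 null tables of the 15 x 2 x 14 patient layout;
end-to-end sign-pattern recovery on 100 replicate 15-patient cohorts run
at the shortest protocol course (7 days, one 4-block session per day) —
the planted hemisphere contrast is far above threshold there, so the
short course loses no discriminative content; and a 3-patient recovering
cohort over 10 days for slope-sign recovery.

## Known limitations

* SNIRF/HDF5 I/O is not built in; recordings are serialized in a
  plain-text session-directory format with the same information content
  (`write_recording()`/`read_recording()`).
* The exact channel adjacency of the clinical montage and the pairing
  rule of the healthy montage are not published; the bundled configs are
  documented reconstructions (the healthy montage declares the 7 central
  sensorimotor pairs whose exact positional mirror exists).
* OLS standard errors assume white residuals (see above).
* The ART implementation requires complete balanced designs; average
  over sessions first.
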