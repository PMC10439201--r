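---
title: "Normative band-power mapping from scalp EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative band-power mapping from scalp EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegnorm)
```

## The problem

Regional band power in resting EEG is spatially heterogeneous even in
healthy brains: alpha rhythms dominate posterior cortex, slow delta
activity is relatively stronger anteriorly, beta is prominent over motor
areas. A focal excess or deficit of power that would be diagnostic in one
region is unremarkable in another, so raw band-power maps are a poor
abnormality detector. The normative-mapping approach addresses this by
building, from a cohort of healthy controls, a per-region, per-band
reference distribution of *relative* band power, and expressing a patient's
values as deviations from that reference:

$$|z_{i,j}| = \left|\frac{x_{i,j} - \mu_{i,j}}{\sigma_{i,j}}\right|,$$

where $x_{i,j}$ is the patient's relative power in region $i$ and band
$j$, and $\mu_{i,j}$, $\sigma_{i,j}$ are the control cohort's mean and
sample standard deviation for that cell. Without a band-specific prior
hypothesis, a region's abnormality indicator is the maximum $|z|$ across
bands. In a temporal-lobe epilepsy cohort, comparing each homologous
region pair's indicator ipsilateral versus contralateral to the
epileptogenic hemisphere with a paired t-test quantifies whether
abnormality lateralizes to the pathological side.

## The processing chain

`run_pipeline()` executes the stages in order; each stage is also an
exported function.

1. **Sensor preprocessing** (`preprocess`): drop an initial settling
   segment (default 30 s), decimate to 250 Hz, bandpass 1–47.5 Hz. The
   upper limit stays below mains frequency and acknowledges that the skull
   strongly attenuates faster activity.
2. **Referencing** (`common_average_reference`): bad channels are dropped
   outright (never interpolated), then the common average is subtracted.
   The same centering is applied to the lead field before inversion.
3. **Source inversion** (`build_sloreta_inverse`, `apply_inverse`): a
   standardized minimum-norm (sLORETA-style) estimate for
   orientation-constrained sources. The minimum-norm kernel is
   $M = G^\top (GG^\top + \lambda C)^{-1}$ and each source's estimate is
   divided by $\sqrt{R_{ii}}$, $R = MG$. This standardization gives exact
   localization of a single active source on a noiseless model — a
   property the test suite verifies exhaustively.
4. **Region collapse** (`collapse_rois`): orientation-constrained sources
   on opposite sulcal walls have opposite signs, so plain within-region
   averaging cancels signal. Each source is sign-flipped to align with the
   region's first principal component before averaging.
5. **Spectral estimation** (`welch_psd`, `relative_band_power`): a 60-s
   epoch, Welch's method with 2-s Hann windows at 50% overlap (0.5 Hz
   resolution), and band powers in delta 1–4, theta 4–8, alpha 8–13, beta
   13–30 and gamma 30–47.5 Hz, each divided by the five-band total.
6. **Normative map** (`build_normative_map`): cellwise mean and sample SD
   (n − 1) across controls, with hemispheric-symmetry
   (`hemispheric_symmetry`) and epoch-robustness (`epoch_robustness`)
   diagnostics, and rank-based comparison against maps from other
   modalities (`crossmodal_correlation`).
7. **Patient scoring** (`zscore_abnormality`, `temporal_subset`,
   `lateralize`) as above.

## Numerical choices

**Filters.** All filtering is zero-phase (forward–backward
`signal::filtfilt`). Decimation is staged with factors of at most 10, each
stage preceded by an 8th-order Butterworth anti-alias low-pass at 80% of
the output Nyquist: designing a 1 Hz high-pass edge directly at a 5 kHz
rate is numerically fragile, whereas per-stage normalized cutoffs stay
well inside the stable range. The bandpass at the target rate is a
4th-order high-pass at 1 Hz cascaded with a 10th-order low-pass at
47.5 Hz; the low-pass order is the smallest for which mains interference
at 60 Hz (and a fortiori 50 Hz) is suppressed by more than 40 dB in power
after the two passes.

**Welch scaling.** Each 2-s segment is mean-detrended and Hann-tapered;
the one-sided density is normalised by $f_s \sum w^2$ so that integrating
the PSD over frequency recovers signal variance (verified against the
analytic power $A^2/2$ of a sine and against white-noise variance).

**Band integration.** Band power is the Riemann sum of the PSD over the
half-open bin range $(lo, hi]$: every 0.5 Hz bin belongs to exactly one
band, shared edges (4, 8, 13, 30 Hz) count once toward the lower band,
and the five band powers partition the total 1–47.5 Hz power exactly.
The synthetic generator uses the same convention in its frequency-domain
synthesis, so the two ends of the pipeline agree bin for bin. On a flat
spectrum the relative powers equal the bandwidth fractions
$(3, 4, 5, 17, 17.5)/46.5$ exactly.

**Regularization.** $\lambda = \mathrm{trace}(GG^\top) / (n_{sensors}
\cdot \mathrm{snr}^2)$ with a default assumed SNR of 3, a conventional
choice for resting EEG; `snr = Inf` gives the unregularized kernel used
for exact-localization checks.

**Sign conventions.** Within a region, flips are the signs of the sources'
loadings on the first principal component (a zero loading keeps +1); the
collapsed series is then aligned to correlate positively with that
component. The global sign per region is irrelevant downstream (band power
is quadratic) but makes outputs reproducible. The collapse is invariant,
up to one global sign per region, to flipping any individual source.

**Degenerate inputs.** Zero total power in a region, zero cohort SD in any
cell, fewer than two subjects, constant vectors in a rank correlation, and
zero-margin contingency tables all raise errors rather than propagating
NaN. A lateralization pair whose ipsi–contra differences are all zero
returns t = 0 (the exact null); constant non-zero differences return a
signed infinite sentinel with a warning.

## The synthetic generator

No public raw recordings accompany this kind of analysis, so the package
ships a generator that emulates the study design end to end and doubles as
the test harness.

* **Geometry** (`make_toy_head_model`): sensors on a unit ring; regions of
  jittered sources around centroids spread deterministically over a
  115°–245° arc in the left half-disc with alternating radii, mirrored to
  the right. Centroids stay clear of the midline so that a parcel's field
  is distinguishable from its mirror image's — near-midline sources are
  genuinely unresolvable from their homologues at low sensor counts, in
  the toy model as in real EEG. Right-hemisphere sources mirror positions
  but draw independent orientations: homologous cortex is symmetric in
  location, not in sulcal folding. Lead-field gains are dipole-like
  (orientation projected on the source-to-sensor direction over squared
  distance) with unit-normalised columns. The defaults (30 sensors, 20
  regions of 3 sources) mirror a clinical 30-channel montage at toy scale.
* **Signals** (`simulate_source_signals`): each region's signal is a sum
  of five band-limited noise components synthesised in the frequency
  domain — white-noise spectra truncated to $(lo, hi]$ and scaled to the
  target variance — so realised band fractions equal the targets exactly,
  components are exactly orthogonal, and there are no filter transients.
  The default regional profile has posterior-dominant alpha and
  anterior-dominant delta on a baseline of roughly 20/15/30/25/10%
  (delta/theta/alpha/beta/gamma), the canonical resting-state topography.
* **Cohorts** (`simulate_cohort`): inter-subject variability is a
  multiplicative lognormal jitter on the target band powers (default SD
  0.10, a choice the source cohort literature does not constrain; it is
  exposed in the spec and config). Patients are identical to controls
  except that one region's band target is elevated so that the *expected*
  z-score equals a requested multiple of the control SD; the SD is
  obtained by a delta-method expansion of the jitter model,
  $\sigma \approx s\, t_b \sqrt{1 - 2 t_b + \sum_c t_c^2}$. The
  abnormality is injected in source space, before sensor mixing, so
  recovering it exercises the complete inverse chain; spectral-estimation
  and inverse-leakage noise are not included in the calibration, so the
  realised $|z|$ sits somewhat below the nominal multiplier.

**What the generator does not emulate:** realistic head conductivity,
ocular/cardiac artifacts, non-stationary brain states, age or sex effects,
and the spatial correlation structure of real cortical noise. Passing
tests therefore demonstrate the correctness and calibration of the
*method* under its stated assumptions, not clinical performance on real
recordings.

## Problem sizes used in the checks

The bundled checks run a 17-control / 22-patient design (the cohort sizes
of the motivating study) on the 30-sensor, 20-region toy model with 60-s
epochs at 250 Hz. The injected-abnormality recovery study repeats the full
chain over 20 seeded cohorts; the null calibration of the lateralization
statistic uses 50 cohorts drawn at the band-power level from the same
population model, where the sensor chain contributes nothing but runtime.
Epoch-robustness comparisons split the 60-s epoch into two 30-s halves.

## Known limitations

* The sLORETA implementation assumes orientation-constrained sources and a
  user-supplied lead field; it does not build head models.
* Relative power conceals global power changes by construction; a uniform
  power elevation across all bands is invisible.
* With 30 sensors, adjacent parcels and near-midline homologues leak into
  one another through the inverse; cohort-level statistics tolerate this,
  but single-subject maps should be read with the corresponding caution.
* Sensitivity to an injected abnormality depends on the orientations drawn
  for the affected region's sources: an occasional cohort draws a
  configuration whose field is weakly observable at the sensors, and the
  abnormality is attenuated below the detection threshold — the same
  orientation dependence that affects real EEG source imaging.
* The lateralization analysis is cohort-based; it does not provide
  individual-patient decisions, and no multiple-testing correction is
  applied across region pairs by default (a Benjamini–Hochberg option
  exists in `lateralize`).
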