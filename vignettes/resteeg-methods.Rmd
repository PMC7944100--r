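---
title: "Resting-EEG biomarkers of working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-EEG biomarkers of working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resteeg)
```

## The scientific question

Resting-state EEG is attractive as a screening biomarker because it is
cheap, fast and task-free. `resteeg` implements a complete analysis chain
asking whether features of 14-channel resting EEG — band power per
electrode and magnitude-squared coherence per electrode pair — correlate
across a cohort with performance on a delayed-match-to-sample (DMS)
working-memory task, summarized per subject as retrieval accuracy (%) and
mean correct reaction time (ms).

The chain is: preprocessing (band-pass 0.5–46 Hz, average re-reference,
bad-channel rejection, artifact subspace reconstruction), Welch spectral
estimation (4-s Hann epochs, 2-s overlap, 0.25 Hz resolution over
1–46 Hz), band powers over the canonical partition (δ 1–4, θ 4–8, α 8–13,
β 13–28, γ 28–46 Hz), coherence

$$\mathrm{Coh}_{xy}(f) = \frac{|G_{xy}(f)|^2}{G_{xx}(f)\,G_{yy}(f)},$$

and electrode-/edge-wise Pearson correlation maps against the behavioral
measures, with two-tailed p-values from the t-transform
$t = |\rho|\sqrt{n-2}/\sqrt{1-\rho^2}$ at $n-2$ degrees of freedom.

Because no human recordings ship with the package, a synthetic-cohort
generator with known ground truth is a first-class module: every claim
the pipeline makes is tested by planting an effect and recovering it.

## The synthetic cohort model

Each subject's resting signal is a sum of independent band-limited
Gaussian noise processes, one per canonical band and channel, synthesized
in the frequency domain so the one-sided spectral density is exactly flat
within each band and zero outside. Band-limited noise was chosen over
sums of sinusoids because flat in-band spectra make every downstream
estimate analytically checkable, and shared-source coherence has a clean
closed form: adding a common band-limited source to two channels with
per-channel shared density $\sqrt{\gamma} D$ yields magnitude-squared
coherence exactly $\gamma$.

Key parameters and defaults (all configurable through `cohort_config()`):

* **Cohort size** 43 and **duration** 60 s per resting condition —
  the cohort conditions the generator emulates.
* **Baseline densities** (μV²/Hz): δ 20, θ 15, α 35.65, β 6, γ 2.
  The alpha level equals the eyes-open occipital alpha group mean;
  δ/θ/β/γ levels are plausible resting densities for older adults chosen
  once so that alpha dominates the eyes-closed spectrum.
* **Eyes-closed boost** 38.80/35.65 ≈ 1.088 on occipital (O1, O2) alpha,
  reproducing the characteristic eyes-closed alpha elevation at its
  reported group levels.
* **Subject heterogeneity** `subject_sd_log = 0.4`: each (channel, band)
  density is multiplied by a mean-normalized lognormal latent,
  $\exp(sZ - s^2/2)$, giving a between-subject density CV of ≈ 0.42.
  Only the occipital-alpha group SD is pinned by the emulated levels
  (CV ≈ 0.11);
  broadband EEG power heterogeneity in aging cohorts is typically much
  larger, and 0.42 sits between the two. The SD is applied on the log
  *density* scale; applying it to log amplitude would double it in power
  and make 43-subject group means essentially irreproducible. Latents are
  independent across channels and bands — the generator deliberately
  ignores spatial correlation and volume conduction, so tests of
  cell-level localization are stricter than real data would be, while any
  procedure exploiting spatial smoothness is not exercised at all.
* **Artifacts**: blinks as 0.4-s raised-cosine transients, 300 μV at the
  forehead and decaying with montage distance (6/min); 0.5-s broadband
  20–46 Hz muscle bursts on random channels (2/min); a 6-s flat channel
  with probability 0.01. Rates are ordinary values for resting recordings
  in older adults, chosen once.

### Two calibrations, decided at design time

The generator defines a configured density as *the density the analysis
pipeline reports*, which requires two deterministic pre-compensations:

1. **Average-reference compensation.** Subtracting the 14-channel mean
   maps independent channel densities $D_c$ to
   $D_c(1-2/n) + \sum_{c'} D_{c'}/n^2$, an ≈ 8% systematic loss. The
   generator inverts this linear map per band and subject
   (`reference_compensation = TRUE`), so targets are met after
   re-referencing.
2. **Taper-leakage compensation.** The Hann taper of the 4-s Welch
   epochs smears just under half a grid bin of density out of each
   brick-wall band edge — a 5% deficit for the 12-bin delta band — and a
   strong band leaks measurably into a weak neighbor (occipital alpha
   into beta). The generator computes the full 5×5 band-response matrix
   of the taper kernel and pre-multiplies densities by its inverse
   (`leakage_compensation = TRUE`).

Both corrections are small; in the rare case an extreme lognormal draw
makes the exact solution negative (a > 5σ event), the affected cell is
floored at a sliver of its target rather than failing the run.

### Planting behavioral correlations

A planted effect (`planted_effect()`) requests a Pearson correlation ρ
between a feature and a behavioral measure. The behavioral covariate is
built as $y = \sum_k a_k z_k + c\,\varepsilon$, where $z_k$ is the
within-cohort standardized *true* value of the k-th planted feature on
the scale the correlation stage measures — relative band power for power
features (the map's default), true edge coherence for coherence features
— and $a = S^{-1}\rho$ solves the joint system for the empirical feature
correlation matrix $S$, with $c^2 = 1 - \rho^\top S^{-1}\rho$. Requests
with $\rho^\top S^{-1}\rho \ge 1$ are rejected as jointly infeasible
(relative powers sharing a channel are strongly anticorrelated, so this
matters in practice). The standardized covariate is then mapped affinely
to the printed behavioral scales: reaction time 673 ± 51 ms, accuracy
91.56 ± 5.02 %, the latter clipped to [0, 100].

Planting against the true feature on the measured scale — rather than
against the log-amplitude latent — is what makes recovery calibrated:
correlating against a latent that enters the measured power through
$e^{0.8 Z}$ would attenuate the recovered coefficient by ~15% through
the lognormal nonlinearity alone. Residual attenuation comes only from
Welch estimation noise (negligible at 60 s; a few percent for narrow
bands at very short durations) and from the accuracy clip (~1–2% for
effects on accuracy).

## Preprocessing

The chain is bad-channel removal → zero-phase band-pass → average
re-reference → ASR, in that order so rejected channels never contaminate
the reference. It is fully deterministic.

* **Filter**: two cascaded 4th-order Butterworth sections (high-pass
  0.5 Hz, low-pass 46 Hz) applied as the squared magnitude response in
  the frequency domain — exactly the zero-phase response of a
  forward-backward pass, without its startup transients (which, on short
  test recordings, measurably inflated band-power noise).
* **Bad channels**: flat if any 5-s window (on a 1-s grid) has
  peak-to-peak < 0.5 μV; peaky if the whole-recording peak-to-peak
  robust z-score (median/MAD across channels) exceeds 5. Neither
  threshold is part of the emulated protocol; both are conservative defaults and
  configurable. With heterogeneous synthetic subjects an occasional
  genuine rejection occurs; downstream tables drop such subjects
  pairwise per cell.
* **ASR**: calibration takes the lowest-RMS 0.5-s windows totaling half
  the recording; the model stores the calibration covariance, its
  eigenbasis, and per-component window-variance statistics. Cleaning
  projects each half-overlapping window onto the basis and rescales any
  component whose variance exceeds `mean + 20·SD` down to that
  threshold, then blends windows by constant-overlap-add. This is a
  deliberate simplification of published ASR — the variance
  classification and subspace attenuation, without the calibration-mixing
  reconstruction. Consequences worth knowing: untouched data pass
  through bit-exactly; total energy never increases; and because
  offending components are rescaled *to the threshold* (≈ 5–7× the mean
  calibration window variance at k = 20), a blink is attenuated but not
  erased — cleaned band powers move toward, not onto, the truth. The
  phrase "20 standard deviations" is read as mean + 20·SD of the
  calibration window variances; the alternative reading (20·SD alone)
  differs negligibly at these values.
* **Duration guard**: at least 60 s must survive cleaning (the emulated protocol's
  retention rule; longer sessions, e.g. 90-s eyes-closed, are available —
  the guard and the simulated duration are both configurable, and the
  pipeline default stays at 60 s).

## Spectral estimation

Welch PSD with Hann tapers, 4-s epochs, 2-s overlap: 0.25 Hz resolution,
density scaled so the one-sided integral equals the taper-compensated
per-segment variance (the emulated protocol fixes the segmentation but
no taper; Hann at 50% overlap is the standard pairing). Band integration assigns
bins to bands by half-open interval $[low, high)$ on the bin center, so
the shared edges 4, 8, 13, 28 Hz are counted exactly once. "Absolute"
band power is reported both as integrated power (μV²) and as mean density
(μV²/Hz, the unit occipital alpha levels are quoted in); correlation
maps default to *relative* power — each band's share of total 1–46 Hz
power — matching the figures that define the headline results, with an
absolute-power switch available.

Auto- and cross-spectra for coherence share one segmentation, so the
coherence ratio is internally consistent and lies in [0, 1] by
Cauchy–Schwarz; with K averaged segments the estimator's bias for
independent signals is ≈ 1/K (≈ 0.034 at 60 s), and a single segment
would give identically 1, so K ≥ 2 is enforced. Coherence is computed over the same 4 s/2 s segmentation as band power —
the only segmentation the protocol defines.

## Behavioral module

Task schedules follow the emulated session structure: 2 blocks × 8
trials, two targets encoded with a 3-s presentation plus a 2-s
consolidation gap (reconciling the protocol's 5-s memorization window
with its 3-s presentation), then 12 test items per trial — an even 6/6
target/distractor split — at 1 s each with uniform 1.6–1.8 s jitter.
Emergent trial length is ≈ 40 s but is not enforced. Responses are
Bernoulli-correct per item; reaction times are lognormal (the standard
positive-skew RT model; the protocol prescribes none) with per-cell means/SDs
defaulting to the printed values, truncated at the 1-s response window
plus 500 ms grace. Non-responses count as incorrect and contribute no
RT, keeping the accuracy denominator equal to presented items. The
Kruskal–Wallis test wraps `stats::kruskal.test` (midrank ties
correction, χ² reference); tests verify it against a brute-force midrank
oracle on all small inputs.

## Correlation mapping

Pearson ρ and two-tailed p per (band, channel) cell — 70 cells — and per
(band, edge) — 455 edges — against a behavioral measure, subjects matched
by id and dropped pairwise. The default multiplicity handling is *none*,
matching the uncorrected p < 0.05 convention of the emulated analysis; a
Benjamini–Hochberg switch is provided as an extension, clearly off by
default. Under an effect-free cohort the fraction of cells with p < 0.05
is verified to sit at the nominal 5%. "Mean reaction time" for maps is
the overall mean correct RT (the emulated analysis does not split it by
condition); a condition-specific choice is available. The edge reported
between frontal and parietal sites is stored symmetrically; the package
takes no position on hemisphere labels where the source is internally
inconsistent.

## Verification studies and problem sizes

Three exported studies recompute the package's headline numbers from
scratch; the test suite and the acceptance script call the same code.

* `recovery_study()` — 200 replicate 43-subject cohorts per planted
  effect (β/P8 ↔ accuracy −0.42, α/P8 ↔ accuracy −0.39, δ/P7 ↔ RT
  −0.31), each run through preprocessing, band power and the map. The
  replicate cohorts are eyes-closed only, artifact-free, and 24 s long:
  this study measures the calibration of the correlation machinery, for
  which Welch noise must be a negligible fraction of between-subject
  variance (24 s suffices even for the 12-bin delta band), while
  artifact robustness is a separate, directly tested property of the
  preprocessing stage. Mean recovered coefficients land within ±0.03 of
  the planted values.
* `occipital_alpha_study()` — one full default cohort (60-s recordings,
  artifacts injected and cleaned); the eyes-closed occipital alpha group
  mean recovers the configured 38.80 μV²/Hz within ±5%. Note the
  default heterogeneity (CV 0.42) makes the *group SD* much larger than
  the reference group SD of 4.32, and the small EC/EO boost is then rarely significant
  in a single cohort — recovering the printed significance would require
  adopting the reference cohort's much smaller between-subject variance, which
  would in turn break planted-correlation recovery at realistic
  estimation noise. The package prioritizes calibrated recovery and
  reports the tension here rather than hiding it.
* `behavior_study()` — 200 replicate cohorts of fully simulated and
  scored sessions; cohort mean target accuracy and correct-target RT
  reproduce 91.56% and 673 ms within sampling error.

## Known limitations

* The generator has no 1/f background, no ERPs, no volume conduction and
  no spatial correlation; passing tests demonstrate pipeline calibration,
  not realism of the simulated EEG.
* ASR is the simplified clip-and-backproject form; real artifacts in
  real recordings will be attenuated less than a full reconstruction
  would achieve.
* EDF and XDF support is deliberately minimal: 16-bit EDF with uniform
  sampling rate and physical units in V/mV/μV; XDF with one regular-rate
  numeric stream. Both are sufficient for interchange with the common
  acquisition tools, not general-purpose readers.
* The behavioral simulator draws per-item correctness independently;
  sequence effects (fatigue, hand-swap costs between blocks) are not
  modeled beyond the per-block hand label.
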