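# resteeg

Resting-state EEG band-power and coherence biomarkers of working-memory
performance, as a tested, reusable R pipeline.

## What this package is for

Resting EEG is cheap, fast and task-free, which makes it a candidate
screening biomarker for cognitive decline. A recurring study design
records a short eyes-open / eyes-closed resting session from a wireless
14-channel headset (10–20 subset: AF3, F7, F3, FC5, T7, P7, O1, O2, P8,
T8, FC6, F4, F8, AF4 at 128 Hz), then a delayed-match-to-sample (DMS)
working-memory task, and asks which resting features correlate across
the cohort with retrieval accuracy (%) and mean reaction time (ms).

`resteeg` implements that whole chain for analysts who want to run or
stress-test it without access to clinical recordings:

* **Preprocessing** — 0.5–46 Hz zero-phase band-pass, bad-channel
  rejection (flat / peak-to-peak outliers), average re-reference, and a
  simplified artifact subspace reconstruction (0.5-s sliding-window PCA,
  components beyond mean + 20 SD of calibration variance rescaled), with
  a 60-s minimum-duration guard.
* **Spectral estimation** — Welch PSD with 4-s Hann epochs and 2-s
  overlap (0.25 Hz resolution over 1–46 Hz); band powers over
  δ 1–4, θ 4–8, α 8–13, β 13–28, γ 28–46 Hz, absolute (μV²/Hz, μV²) and
  relative; magnitude-squared coherence for all 91 channel pairs,

  Coh<sub>xy</sub>(f) = |G<sub>xy</sub>(f)|² / (G<sub>xx</sub>(f) · G<sub>yy</sub>(f)).

* **Behavior** — DMS schedules (2 blocks × 8 trials × 12 test items,
  1.6–1.8 s jitter), response simulation and scoring, Kruskal–Wallis
  group tests.
* **Correlation mapping** — Pearson ρ with two-tailed p from
  t = |ρ|√(n−2)/√(1−ρ²) on df = n−2, per (band, electrode) cell (70) and
  per (band, edge) (455), uncorrected by default with an optional BH
  switch.
* **Synthetic cohorts** — a generator with known ground truth
  (band-structured noise, eyes-closed occipital alpha elevation, blinks /
  muscle bursts / flat channels, and *planted* Pearson correlations
  between features and behavior), so every stage is verifiable end to
  end.

## Worked example

Plant a single ground-truth effect — eyes-closed relative beta power at
P8 correlating ρ = −0.42 with task accuracy — in a 43-subject cohort,
run the full pipeline, and look at the accuracy correlation map:

```r
library(resteeg)

cfg <- run_config(
  cohort = cohort_config(
    n_subjects = 43, duration_s = 30, master_seed = 42,
    planted_effects = list(planted_effect("P8", "beta",
                                          "accuracy_pct", -0.42))),
  min_duration_s = 30)

bundle <- run_pipeline(cfg, "demo-run", verbose = FALSE)
cm <- bundle$maps$accuracy_pct
head(cm[order(cm$p), ], 3)
#>     band channel    rho       p  n
#> 44  beta      P8 -0.417 0.00537 43
#> 28 alpha      T7  0.351 0.02099 43
#> 54 gamma      O1  0.245 0.11259 43

bundle$contrast
#>     condition  mean    sd  n  kw_H   kw_p
#> 1 eyes_closed 37.68 11.63 43 2.019 0.1554
#> 2   eyes_open 34.53 10.57 43 2.019 0.1554
```

The planted cell comes out on top at ρ = −0.417 (p = 0.0054): the
pipeline recovers the effect it was given, at its size, and the
remaining 69 cells behave like null cells. The eyes-closed occipital
alpha mean (37.7 μV²/Hz here) sits at the generator's configured
eyes-closed level of 38.80 μV²/Hz, above the eyes-open 35.65 μV²/Hz.
`run_pipeline()` also writes every stage table (band powers, coherence
edge lists, behavior, maps, cleaning reports) as CSV with a checksummed
manifest; identical configurations give byte-identical outputs.

A thin command-line wrapper is installed at
`inst/cli/resteeg-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/resteeg-pipeline.R", package="resteeg"))')" \
  run-all --config run.yaml --out results/
```

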