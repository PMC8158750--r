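# bcgvf — ventricular fibrillation detection from ballistocardiography

Ballistocardiography (BCG) records the recoil vibrations of the body caused
by cardiac ejection with a non-contact sensor (e.g. a piezoelectric film
under a mattress), sampled here as a single channel at 125 Hz. During
ventricular fibrillation (VF) the coordinated heartbeat collapses into
disordered oscillation: the quasi-periodic "W-shaped" beat clusters of sinus
rhythm (SR) disappear and the signal becomes an aperiodic, random-amplitude
oscillation. `bcgvf` implements a complete detection pipeline for 7 s BCG
segments, for researchers working on unobtrusive cardiac monitoring:

1. **Preprocessing** — 7-level Daubechies-6 wavelet decomposition; the
   cardiac band is reconstructed from details d3–d7, and a leaky LMS
   adaptive filter (64 taps, α = 1, μ = 10⁻⁸) cancels the 3 s-period
   ventilator pulse artifact using a noise reference built from per-window
   extrema plus the d7 component, Savitzky–Golay smoothed. Recordings are
   then split into 875-sample segments (stride 875/375/125 for SR/MA/VF).
2. **Transformation** — each segment is re-decomposed and reconstructed as
   |cc₆|·d6 + d3 + d4 + d5; its autocorrelation
   r_k = (1/c₀N) Σ (x_t−x̄)(x_{t+k}−x̄) is normalized to [1,2] and squared;
   a discrete Stockwell transform (frequency-scaled Gaussian voices,
   σ_t = 1/f) over 1–20 Hz yields a power map S(f,t), cropped to the middle
   period [hbl/2+1, N−hbl] where hbl is the heartbeat cycle length estimated
   by maximizing the mean adjacent-beat correlation over window lengths
   44–150 samples.
3. **Features** — 22 values per segment: mean/variance/skewness/kurtosis of
   the slice-correlation (SC), instantaneous-frequency (IF), quantized
   amplitude (QA), peak-interval (PI) and spectral-density (SD) sequences,
   plus the FWHM of the dominant spectral peak and the time-domain range RM.
4. **Statistics** — Mann–Whitney U relevance tests per class pair with
   Benjamini–Yekutieli FDR adjustment (unclipped, per-column, m = 22), and
   average-linkage hierarchical clustering of features at distance
   √(2(1−r)); a fixed 13-feature subset (1, 2, 3, 4, 7, 10, 11, 14, 16, 17,
   19, 21, 22) or a data-driven re-selection.
5. **Classification** — random undersampling of training folds, logistic
   regression or a random forest (bagged Gini CART, compiled), evaluated
   intra-subject (systematic 10-fold) and inter-subject (leave-one-subject-
   out) with SEN, SPE, PRE, F1, bACC and MCC.

Because no public VF-BCG recordings exist, the package ships a seeded
synthetic cohort simulator (`generate_sr`, `generate_vf`, `generate_ma`,
`generate_cohort`) emulating beat morphology variation across subjects,
heart rates 50–170 bpm, respiration baseline, ventilator pulses, motion
artifacts and sensor noise. See `vignettes/bcgvf-methods.Rmd` for what the
simulator does and does not establish.

## Worked example

```r
library(bcgvf)
prof <- subject_profile("pig01", beat_amplitude_scale = 1,
                        beat_morphology_seed = 7, baseline_heart_rate = 75,
                        noise_sd = 0.15)
sr <- generate_sr(14, prof, seed = 1)
vf <- generate_vf(14, prof, seed = 2)
seg_sr <- segment_recording(preprocess_recording(sr, lms = FALSE))[[1]]
seg_vf <- segment_recording(preprocess_recording(vf, lms = FALSE))[[1]]
rbind(SR = extract_features(seg_sr),
      VF = extract_features(seg_vf))[, c("SC_mean", "SC_var", "QA_mean",
                                         "FWHM", "RM")]
```

```
   SC_mean SC_var QA_mean  FWHM    RM
SR   0.846  0.011   0.119 4.611 2.236
VF   0.615  0.036   0.272 5.163 4.046
```

The SR segment's adjacent Stockwell slices correlate strongly (`SC_mean`
0.85 vs 0.62) and tightly (`SC_var` 0.011 vs 0.036) — the rhythmic beat
repeats in the time-frequency map — while the fibrillatory segment spreads
its marginal amplitude (`QA_mean`) and dominant spectral peak (`FWHM`)
wider. `estimate_hbl(seg_sr)` returns 101 samples, the planted 75 bpm beat
period (100) within jitter.

A full cohort run:

```r
rep <- run_pipeline(pipeline_config(n_subjects = 23, paradigm = "loso",
                                    repeats = 2, seed = 11), "out/")
#> <bcg_report> RF / loso, 2 repeat(s), 13 feature(s)
#>   SEN  0.943 (0.004)   SPE  0.931 (0.019)   ...
```

A command-line front end (`inst/cli/bcgvf`) exposes `simulate`,
`preprocess`, `extract`, `analyze`, `train-eval` and `run-all` subcommands.

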