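# gabagamma

Multimodal analysis linking the properties of visually induced
gamma-band oscillations in primary visual cortex (V1), measured with
MEG, to GABA-A (benzodiazepine-site) receptor density measured with
flumazenil PET — for researchers studying the GABAergic basis of
cortical rhythms, and for anyone who needs a fully testable synthetic
benchmark for MEG beamforming + PET parametric-imaging pipelines.

## What it computes

**MEG side.** Sensor epochs are decomposed with Morlet wavelets of
width 7 (`sigma_t = m/(2*pi*f)`), giving time-resolved sensor
cross-spectral densities C(f, t). An event-related DICS beamformer
`W = (L' Cr⁻¹ L)⁻¹ L' Cr⁻¹` (Cr = Re C + λ·mean(diag Re C)·I, λ = 0.05)
with a spherical (Sarvas) forward model projects power onto a source
grid; power is smoothed over 13 time bins, averaged over ±4 Hz above
40 Hz, baseline-normalised, and summarised per subject as the gamma
(40–100 Hz), alpha (7–14 Hz) and beta (15–30 Hz) peak frequency, timing
and amplitude in V1.

**PET side.** A partial-saturation Scatchard model converts late-frame
flumazenil images into receptor-density parametric maps
`B'max(v) = (C(v) − F)(1 + Kd_app/F)`, with the free concentration F
estimated in the pons and Kd from the frame-wise occipital Scatchard
line; maps are smoothed (15×15×21 mm FWHM) and aggregated as the total
density over the unique V1-PET voxel set.

**Statistics.** Spearman and Pearson correlations with two-sided
df = n−2 p-values, the JZS default correlation Bayes factor

    BF10 = sqrt(n/2)/Γ(1/2) ∫ (1+g)^((n−2)/2) [1+(1−r²)g]^(−(n−1)/2) g^(−3/2) e^(−n/(2g)) dg,

leave-2-out bootstrap 95% limits, confound regression (V1 surface area,
gray-matter density), and random-voxel specificity nulls.

**Synthetic cohorts.** `make_cohort()` + `simulate_meg_recording()` +
`simulate_pet_dynamic()` generate subjects whose total V1 receptor
density is coupled positively to gamma peak frequency and negatively to
gamma amplitude, with known ground truth — so the whole pipeline is
verifiable by parameter recovery.

## Worked example

```r
library(gabagamma)

config <- cohort_config(n_subjects = 10, seed = 42)   # truth rho ~ +/-0.75
study  <- simulate_cohort_study(config)               # simulate + both pipelines
rep    <- run_full_analysis(study$features, study$density,
                            study$confounds, seed = 42)
rep$report[, c("correlation_name", "spearman_rho", "spearman_p",
               "pearson_r", "bf10", "ci_low", "ci_high")]
```

```
          correlation_name spearman_rho spearman_p pearson_r  bf10  ci_low ci_high
       gamma_frequency_raw       0.6319     0.0500     0.704 3.137  0.4148   0.709
 gamma_frequency_regressed       0.3252     0.3592     0.403 0.459  0.0732   0.683
       gamma_amplitude_raw      -0.6485     0.0425    -0.705 3.150 -0.8095  -0.500
 gamma_amplitude_regressed      -0.4788     0.1615    -0.558 0.971 -0.7857  -0.286
          gamma_timing_raw       0.3137     0.3775     0.353 0.388 -0.0127   0.676
    gamma_timing_regressed       0.0502     0.8905     0.195 0.270 -0.4439   0.269
```

Reading the output: this cohort was generated with a positive
density–frequency and negative density–amplitude coupling; the
recovered raw-density rows show exactly those signs (rho = 0.63 and
−0.65; the realised truth coupling in this particular 10-subject draw
was 0.66 and −0.82). `bf10 > 1` favours the presence of a correlation
(e.g. 3.1 for both gamma rows); `ci_low`/`ci_high` are leave-2-out
bootstrap 95% limits of rho. Timing rows are null-consistent, as
generated. The regressed rows remove V1 surface area and gray-matter
density, which in this synthetic cohort are pure noise confounds.

The reference worked example for the Bayes factor:

```r
jzs_cor_bf(0.75973, 10)   # 6.006452
jzs_cor_bf(-0.61411, 10)  # 1.415973
```

## Command-line helpers

```sh
Rscript inst/scripts/simulate.R  --out data/ --subjects 10 --seed 1
Rscript inst/scripts/correlate.R --features features.csv --density density.csv \
    --confounds confounds.csv --seed 1 --out report/
```
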