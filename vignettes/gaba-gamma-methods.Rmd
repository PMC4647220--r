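---
title: "Linking visual gamma oscillations to GABA-A receptor density: models and methods"
author: "gabagamma authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking visual gamma oscillations to GABA-A receptor density: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabagamma)
```

# The scientific question

Gamma-band oscillations (roughly 40--100 Hz) in visual cortex are thought
to arise from the interplay of pyramidal cells and GABAergic
interneurons, so their properties should reflect the strength of
inhibitory neurotransmission. `gabagamma` implements a multimodal
analysis that relates, across subjects, three properties of the visually
induced V1 gamma response measured with MEG --- its peak frequency, peak
timing and peak amplitude --- to the density of GABA-A (benzodiazepine
site) receptors in the same region measured with flumazenil PET.
Receptor density is expected to correlate **positively** with gamma peak
frequency and **negatively** with gamma amplitude.

Because no raw multimodal dataset of this kind is publicly deposited,
the package ships a synthetic-cohort generator with *known*
GABA-A--gamma coupling. Every analysis stage can therefore be verified
by parameter recovery: simulate a cohort whose ground truth is known,
push it through the full pipeline, and compare what comes out with what
went in.

# The MEG chain

## Sensor model and forward solution

Subjects are modelled with a spherical volume conductor. Sensors are
ideal point magnetometers on a spherical cap (default 102 sensors,
radius 10 cm) with radial orientations; a realistic gradiometer array is
deliberately not reproduced, because only the validity of the forward
model matters for recovery tests. The field of a current dipole inside
a homogeneous conducting sphere, including volume currents, has the
closed-form Sarvas solution implemented in `sarvas_field()`; radial
dipoles are magnetically silent, so `leadfield()` returns the fields of
two *tangential* unit dipoles per grid point. The tests cross-check the
closed form against an independent numeric construction: outside a
spherical conductor the radial field component depends only on the
primary dipole, and the full field follows from the magnetic scalar
potential obtained by radial quadrature.

## Time-frequency decomposition

Sensor epochs (600 Hz, -200 to 800 ms around stimulus onset) are
decomposed with Morlet wavelets of width `m = 7` cycles
(`sigma_t = m / (2 pi f)`, L2-normalised). The analysis grids follow
the reference layout: frequencies 4--15 Hz at 0.25 Hz, 15--30 Hz at
0.5 Hz and 36--104 Hz at 2 Hz; time instants every 17 ms. One
discrepancy is worth stating: with a 17-ms step the pre-stimulus window
[-200, 0) ms holds 12 bins (a 16.67-ms step would hold 13); the package
uses the stated 17-ms step and defines the baseline as all bins with
t < 0. Nodes whose full +/-3-sigma wavelet support does not fit into
the epoch (always true below ~8 Hz) are computed with truncated support
but flagged in a validity matrix rather than dropped, mirroring common
practice of analysing low frequencies with edge effects acknowledged.

## Event-related DICS beamformer

`dics_power()` implements the frequency-domain minimum-variance
beamformer: per grid point, `W = (L' Cr^-1 L)^-1 L' Cr^-1`, with
`Cr = Re(C) + lambda * mean(diag(Re(C))) * I` and diagonal loading
`lambda = 0.05` (5% of mean sensor power). The original erDICS
publication names the method but not the algebra, so these are standard
choices, all configurable. Power is the largest eigenvalue of the
2 x 2 filtered real CSD over the two tangential orientations, hence
non-negative, and `W L = I` (unit gain) holds by construction. By
default one filter per frequency is computed from the time-averaged
(baseline + active) CSD and applied at every time bin; because power
then depends linearly on the per-bin CSD, smoothing power after
filtering equals filtering smoothed CSDs. A `per_bin` filter mode is
provided since the original operationalisation is not documented.
`dics_power_coefs()` is an algebraically identical fast path that
projects per-trial wavelet coefficients through the filters before
trial averaging (the agreement of the two routes is a unit test), and
beamforming can be restricted to a subset of points (exact, because
filters are per-point independent).

## Response normalisation and peaks

Power is smoothed along time with a 13-bin moving average (the bin and
six neighbours each side; windows shrink at epoch edges rather than pad
with invented data). At and above 40 Hz each bin is replaced by the
average over +/-4 Hz (the 40 Hz value becomes the 36--44 Hz mean). The
baseline per (point, frequency) is the mean pre-stimulus power, and the
modulation is either *absolute* --- `(power - baseline) / SD_band`,
with `SD_band` the SD of baseline power over all V1 points and all band
frequencies, separately for the low (4--30 Hz) and high (>= 36 Hz)
bands, which removes head-geometry gain differences --- or *percent*
(`100 * (power - baseline) / baseline`). Absolute-mode modulation is
invariant to global sensor gain rescaling (a property test).

Per-subject peaks are extracted from the V1-averaged response within
0--600 ms: gamma (search range 40--100 Hz) as the maximum, alpha
(7--14 Hz) and beta (15--30 Hz) as the deepest suppression (most
negative value), since those bands are suppressed by the stimulus. The
peak amplitude is read from the same smoothed, band-averaged array used
everywhere else (whether the original analysis used smoothed or raw
bins is not documented; smoothed is the consistent choice). Ties break
towards lower frequency and earlier time, deterministically, with a
message. Theta (4--7 Hz) is computed by the machinery but has no peak
default, mirroring its null modulation. Group-level stimulation maps
use a paired two-sided t-test (post 0--600 ms vs pre -200--0 ms band
averages) at p < 0.005, uncorrected; zero-variance points are excluded
as undefined.

# The PET chain

## Partial-saturation forward model

A single injection of mixed labelled/unlabelled flumazenil at partial
saturation yields, at pseudo-equilibrium, voxel concentrations
`C(v) = F + B(v)` with bound
`B(v) = Bmax(v) * F / (F + Kd_app)`; the pons is essentially
receptor-free, so its intensity estimates the free concentration `F`.
The synthetic dynamic acquisition has 12 frames; the five late frames
(20--55 min) carry declining free-ligand fractions
`phi = (0.50, 0.24, 0.13, 0.08, 0.05)` of the static `F` (summing to 1,
so the *summed* static image is exactly at the nominal equilibrium) with
frame-level occupancies consistent with the static saturation law.
Frame noise is Gaussian with SD proportional to the square root of
frame activity (as for count-limited data), normalised so the static
image carries the configured noise fraction (default 5% of `F`).

## Estimation

`static_image()` sums frames 8--12 (1-based labels). The apparent
dissociation constant cannot be identified from a single static image:
with one `F`, the across-voxel Scatchard plot of `B/F` against `B` is
the identity line `y = x / F` for *any* data, so the regression is
degenerate by construction. Occupancy variation from a single injection
exists only across *time*, so `fit_scatchard()` forms frame-wise pairs
(`B_t / F_t`, `B_t`) from the pons free and occipital-ROI bound
concentrations over the late frames and fits the Scatchard line across
frames (slope `-1/Kd_frame`). The frame-level constant is converted to
the static scale so that the closed-form parametric image
`B'max(v) = (C(v) - F) * (1 + Kd_app / F)` inverts the forward model
*exactly* in the noise-free limit (a 1e-6 relative-error test). Since
`B/F` is strongly heteroscedastic in low-activity washout frames, a
weighted fit (`weights = "free2"`, i.e. `F_t^2`) is available and is the
pipeline default; plain OLS remains the single-call default. Negative
bound values (possible in receptor-free tissue under noise) are clipped
to zero with a count recorded.

Whether apparent Kd should be fitted per subject is genuinely open. It
is a property of the ligand--receptor system and is expected to be
stable across subjects, while a 5-point per-subject fit at realistic
noise has a heavy-tailed `-1/slope`; the cohort pipeline therefore
pools the Scatchard across subjects (common slope, per-subject
intercepts and free concentrations). Per-subject fits remain available
and tested.

`smooth_map()` applies a separable Gaussian of FWHM 15 x 15 x 21 mm
(matching the beamformer's effective resolution) with half-sample
reflective boundaries, which conserve the total image mass.
`v1_total_density()` maps each MR-space V1 voxel to its nearest PET
voxel, de-duplicates, and returns the **sum** of B'max over the unique
set --- a measure deliberately sensitive to V1 size, which is why V1
surface area and gray-matter density are later regressed out.

# Correlation battery

For each paired sample the package reports Spearman's rho with a
two-sided p from the t approximation on n - 2 degrees of freedom (the
reference analysis' printed Pearson p-values pin down this convention;
an exact permutation p is compared against it in a property test),
Pearson's r with the same convention, the JZS default correlation Bayes
factor, and leave-2-out bootstrap 95% limits. The Bayes factor is

$$BF_{10} = \frac{\sqrt{n/2}}{\Gamma(1/2)} \int_0^\infty
  (1+g)^{(n-2)/2}\,\bigl[1+(1-r^2)g\bigr]^{-(n-1)/2}\,
  g^{-3/2} e^{-n/(2g)}\,dg,$$

evaluated by adaptive quadrature (relative tolerance 1e-8, divergence
is an error); it is symmetric in the sign of r, strictly increasing in
|r| and in n (for |r| > 0), and is cross-checked against a Monte-Carlo
estimate of the same integral (g sampled from its inverse-gamma
mixing density). The bootstrap drops 2 of the n subjects uniformly
without replacement, 200 times (resamples necessarily repeat pairs:
there are only 45 distinct pairs at n = 10), and takes the 2.5/97.5
percentiles with linear interpolation --- the percentile method, since
nothing more elaborate is documented. Confound regression is ordinary
least squares with intercept on V1 surface area and gray-matter
density. All p-values are uncorrected throughout.

Specificity nulls (`random_voxel_nulls()`) rebuild the density--feature
correlation from 100 fully random and 100 contiguous (region-grown,
6-connectivity) voxel sets, each exactly as large as the V1 set and
with every voxel more than 4 cm from V1.

# The synthetic cohort: what it emulates, and what not

`cohort_config()` fixes the generative conditions: 10 subjects by
default; gamma peak frequencies spread over 45--85 Hz (population SD
8 Hz around the 65 Hz centre --- the population distribution is not
printed anywhere, so a wide uniform-like spread spanning the analysis
band was chosen); amplitudes (mean 1, SD 0.25 normalised units);
latencies near 300 ms. Coupling is imposed on the **total V1 B'max**:
the slopes and residual SDs are derived so that the population
correlation with total density is `target_rho` (default 0.75) in
magnitude, positive for frequency and negative for amplitude --- the
headline effect sizes of the reference analysis. The voxelwise density
field has a receptor-rich medial occipital compartment (10 units/voxel
with a fixed mild gradient, scaled by a per-subject factor), a
moderate background (4 units, scaled by an *independent* subject
factor so that far-from-V1 nulls and the whole-brain control are not
trivially coupled), a receptor-free pons, and small per-voxel texture.
The occipital compartment extends a margin beyond V1 so that after
15--21 mm smoothing the V1 neighbourhood is still dominated by the same
subject factor. The PET protocol operates at ~80% occupancy
(`kd_app = free_conc / 4`), a deliberately well-conditioned
partial-saturation design: at flatter washout or lower occupancy the
frame-wise Kd becomes unidentifiable at 5% noise.

MEG recordings forward-project a coherent V1 patch carrying the gamma
burst (Gaussian envelope, sigma 80 ms), plus 10 Hz and 20 Hz rhythms
whose amplitudes fall by the subject's suppression depths after
stimulus onset, with random per-trial phases (the gamma response is
induced, not phase-locked). Sensor noise is spatially correlated
(30-mm Gaussian correlation plus an independent component) pink noise,
default 50 fT SD --- chosen so that a realistic number of trials yields
the prominent trial-averaged V1 gamma response the paradigm is known to
evoke. Blink trials (default 15%) carry a stereotyped biphasic EOG
deflection exceeding the 150 uV rejection threshold plus a fixed
frontal field pattern; only the rejection rule is under test, not blink
physiology.

What the generator does **not** emulate --- and hence what passing
recovery tests do *not* establish about real data: realistic head
anatomy and per-subject warping (one shared grid stands in for the
template-to-individual mapping), gradiometer pickup and noise
cancellation, non-Gaussian PET count statistics, radioligand kinetics
beyond the pseudo-equilibrium late-frame model, attenuation or motion
artifacts, and any behavioural component of the task.

# Numerical choices and problem sizes

Numerical points a maintainer should know: wavelet kernels flush
far-tail envelope values (< 1e-12 of the peak) to exact zero ---
subnormal operands otherwise stall the BLAS matrix products the
decomposition is built on; the 2 x 2 orientation eigenproblem is solved
in closed form; Cholesky factorisation failure of the loaded CSD is
reported with advice to raise `lambda`; grid indices are 1-based
throughout, as is idiomatic in R, and PET frame labels are 1-based to
match the "frames 8--12" convention.

The simulation studies in the test suite run at a reduced, documented
problem size chosen to keep a 200-cohort recovery study tractable on a
single core: 32 sensors, 12 trials per subject, a 10-mm posterior grid
(125 points, ~7 in V1, beamformed at the V1 patch), the gamma-only
frequency grid, and a 24 x 24 x 32 PET volume with 4 x 4 x 2.42 mm
voxels. Peak-frequency recovery is at grid resolution (+-2 Hz), so
conclusions about sub-bin frequency effects are outside scope.
Single-subject examples and the localisation benchmark use a 6-mm grid
with 48 sensors, where the DICS localisation error at sensor-level
SNR 3 is at most one grid spacing in at least 95% of runs.

# Known limitations

The beamformer assumes uncorrelated sources; the simulated V1 patch is
coherent, which is the worst case for an adaptive beamformer, and
amplitude estimates inherit some cancellation-related variability (rank
correlations with truth are high but not perfect at the reduced trial
count). The pooled-Kd default trades per-subject independence for a
well-conditioned estimate; with few frames and small ROIs the
per-subject variant has a heavy-tailed Kd. Bootstrap limits at n = 10
from 200 leave-2-out resamples are descriptive, not exact confidence
procedures. None of the synthetic defaults were calibrated to
unpublished inter-subject ranges (amplitude and density spreads are
configurable, not validated).
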