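---
title: "Methods: semipartial connectivity and transversal segment analysis on BOLD phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semipartial connectivity and transversal segment analysis on BOLD phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehconn)
```

## What the package computes

`ehconn` implements a complete functional-connectivity analysis of the
entorhinal-hippocampal circuitry, from 4D BOLD runs to group statistics:

1. **Task GLM per subject.** Spike volumes are detected from the global mean
   intensity (scan-to-scan change above 1.3% of the run mean) and from
   framewise displacement (sum of absolute translation differences above
   0.3 mm). The design holds one HRF-convolved regressor per condition
   (scene, object, baseline — baseline is modelled explicitly because the
   contrasts of interest are *versus baseline*), six motion columns, one
   one-hot column per spike, and an intercept. Ordinary least squares is fit
   per voxel; the residuals feed the connectivity analyses, the betas feed
   the scene/object-versus-baseline contrast maps, which are smoothed with a
   1.5 mm FWHM Gaussian kernel.
2. **Semipartial seed-to-voxel connectivity.** Seed masks are first cleaned
   of low-intensity voxels (temporal mean more than 2 SD below the ROI mean
   of voxel means — the reference population is the ROI itself, a choice the
   wording of published protocols leaves open). All series are band-pass
   filtered to 0.01–0.1 Hz, voxel series are residualized against nuisance
   regressors (white-matter and CSF means, motion), and the seed series is
   additionally residualized against the *other* seeds, so that the
   correlation captures variance uniquely explained by the seed. The
   correlation is Fisher-z transformed with clipping at `1 - 1e-7`.
   The residualization side matters and toolboxes differ: here the seed
   (predictor) is cleaned of the competing sources; voxel series are cleaned
   of nuisance only.
3. **Winner-take-all parcellation.** One-sample t-maps across subjects are
   computed per cortical source (RSC, PHC, A35, A36); each entorhinal voxel
   is assigned to the source with the maximum T, provided that T exceeds 3.1
   (one-sided: positive connectivity). Ties are broken by the fixed source
   order and logged. With two hemispheres, per-source voxel counts are
   equalized by keeping the N highest-T voxels, N being the smaller
   hemisphere count; with one hemisphere the operation is the identity.
4. **Transversal segmentation.** Per coronal slice, the subiculum is cut
   into five equal-width bins along the medial-lateral axis
   (`label = 1 + floor(5 (x - min)/(max - min + 1))`), and CA1 into three
   60° sectors around the chord connecting the two maximally distant voxels
   of the slice (lexicographic tie-break; the published protocol does not
   define the "outer borders" operationally, so the maximum-distance pair is
   used as a deterministic surrogate). Labels run proximal (1) to distal.
   Angle bins are half-open except the last, so every voxel gets exactly one
   label. Segment estimates are averaged per slice and then across slices
   with equal slice weights; a voxel-count-weighted average is a documented
   alternative, deliberately not the default because the extraction protocol
   being emulated averages *along* the slices.
5. **Hierarchical testing cascade.** Stage 1: a 4 (seed) x k (segment)
   repeated-measures ANOVA per target region (subiculum: k = 5; CA1: k = 3),
   interaction p-values Benjamini-Hochberg-corrected across regions. Stage
   2: within each significant region, per-seed one-way ANOVAs across
   segments, FDR-corrected within the region. Stage 3: pairwise seed x
   segment interactions among the stage-2 survivors; the published
   description does not state an FDR family for this confirmatory stage, so
   it is reported uncorrected and flagged in the decision log. Content
   effects use condition x region (or x segment) ANOVAs with FDR-corrected
   post-hoc paired t-tests, run only when the interaction is significant.

The repeated-measures ANOVA uses the classical univariate decomposition,
testing each effect against its own subject-by-effect stratum, with **no
sphericity correction by default**: an a x b within design with n subjects
has interaction df exactly ((a-1)(b-1), (a-1)(b-1)(n-1)), e.g. (12, 372)
for 4 x 5 with n = 32, (6, 186) for 4 x 3 and (3, 93) for 2 x 4 — the df
convention of the analyses being reproduced. A Greenhouse-Geisser epsilon
is available via `rm_anova(..., gg = TRUE)`.

## The synthetic phantom

No voxel-level data are distributable with the package, so every stage is
validated on a phantom with known ground truth. The phantom emulates:

* four cortical source ROIs driven by independent latent signals, band
  limited to 0.01–0.1 Hz (white Gaussian series masked in the FFT domain
  and standardized — simple and spectrum-exact);
* an EC block of four hidden 64-voxel subregions, each following one
  latent with unit weight;
* subiculum (10 voxels wide, 8 coronal slices) and CA1 (a 9-voxel
  semicircular arc per slice, so the 60° sector rule is meaningful) sheets
  whose latent weights interpolate linearly between configurable proximal
  and distal values;
* scene/object/baseline events (3 s stimuli; mini-blocks of two stimuli
  alternating between scene and object, bracketed by ten-stimulus baseline
  blocks), with a scene-amplitude boost confined to the PHC-driven EC
  subregion and, via a proximal-to-distal ramp, the distal subiculum;
* i.i.d. Gaussian voxel noise, a constant intensity offset of 100, smooth
  random-walk motion parameters, and +3% global-intensity spikes on
  randomly selected volumes (chosen to exceed the 1.3% detection threshold
  by design).

The default gradient weights encode the qualitative topography under
study — PHC-driven connectivity rising toward the distal subiculum,
A35- and RSC-driven connectivity rising toward the proximal subiculum,
RSC-driven connectivity rising toward distal CA1, and a flat A36
profile — with magnitudes (0.2–1.0) chosen once to give a comfortably
detectable but not degenerate signal-to-noise ratio at unit noise SD.
They are study conditions, not tuning knobs.

The phantom's "coronal" axis is the second grid axis and medial-to-lateral
is the first; both are recorded in the label-map metadata (together with
the proximal direction) so segmentation never guesses orientations. The
proximal ends of both sheets sit at the lateral side, adjacent to one
another, mirroring the anatomical arrangement in which distal CA1 borders
the proximal subiculum.

What the phantom deliberately does **not** model: physiological and
vascular noise spectra, spatial autocorrelation of noise, multi-band
artifacts, subject-specific anatomy or co-registration error, and the
event-related old/similar recognition micro-structure of the behavioural
task (only condition-level regressors matter downstream). Passing tests
therefore demonstrate the correctness of the computations and the internal
consistency of the pipeline, not robustness to the full noise structure of
real 7T data.

## Problem sizes and numerical choices

The default configuration is desk-scale: a 24 x 24 x 12 voxel grid, 16
subjects, one run of 240 volumes at TR 2.4 s. The full-scale acquisition
(32 subjects, two runs of 332 volumes) is valid configuration, and all
statistics reproduce the full-scale degrees of freedom when given n = 32
tables. Type-I calibration uses 200 null-phantom replicates at 130 volumes
per run, enough for about three cycles of the 0.01 Hz low cutoff (shorter
runs trigger a logged warning in the band-pass filter). With multiple runs,
residuals are standardized per run and voxel and concatenated in time before
filtering; the alternative (per-run connectivity, then averaging) is not
implemented, a choice the emulated protocol leaves open.

Numerical details worth knowing:

* The band-pass filter is a zero-phase FFT mask — exact in the passband and
  deterministic, at the cost of mild ringing for signals far outside the
  band; it always removes DC.
* Fisher transforms clip correlations at `1 - 1e-7`, so a perfect
  correlation maps to z ≈ 8.5 rather than infinity.
* One-sample t-maps report a signed-infinity sentinel at voxels with zero
  between-subject variance (it wins any winner-take-all comparison, which
  is the desired behaviour for noise-free phantoms) and log a warning.
* Degenerate slices (fewer distinct coordinates than bins; zero in-plane
  extent) are skipped with a warning rather than aborting the run.
* Effects with zero effect variance report F = 0, p = 1 instead of 0/0.
* All randomness flows from a single integer seed per group; identical
  configurations are bit-identical, including report JSON files.

## Limitations

Semipartial residualization uses the *estimated* seed series, so with
correlated sources some shared variance leaks into each "unique" seed
component; on flat-gradient phantoms this produces small apparent profile
variation through the position-dependent voxel variance (the denominator of
the correlation), which the cascade may legitimately flag at high SNR. The
framewise displacement uses translations only (the motion threshold of the
emulated artifact-detection tool is stated in mm); rotations are ignored.
The hippocampal head and tail, pre/parasubiculum subdivisions, anatomical
naming of seed clusters, and multivariate/representational connectivity are
out of scope.
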