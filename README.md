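# ehconn

Functional connectivity and information processing in the
entorhinal-hippocampal circuitry, as a tested, reproducible R pipeline.

High-resolution fMRI studies define functional subregions of the entorhinal
cortex (EC) by their *preferential* connectivity to cortical sources — the
retrosplenial cortex (RSC), parahippocampal cortex (PHC) and perirhinal
areas 35 and 36 — and then ask how those EC seeds map onto the transversal
(proximal → distal) axis of the hippocampal subiculum and CA1, and where
scene versus object information is processed. This package implements that
entire analysis chain for researchers who want to run it, test it, or probe
its operating characteristics on data with known ground truth:

* **Synthetic BOLD phantoms** (`phantom_config()`, `simulate_group()`):
  groups of 4D runs with four latent cortical sources, hidden EC
  subregions, subiculum/CA1 sheets with imposed transversal connectivity
  gradients, scene/object/baseline task responses, noise, motion and
  intensity spikes — everything downstream is testable without any data
  download.
* **Task GLM** (`detect_spikes()`, `build_design()`, `fit_glm()`,
  `glm_contrast()`, `smooth_volume()`): spike regressors from global
  intensity (>1.3%) and framewise displacement (>0.3 mm), HRF-convolved
  condition regressors, per-voxel OLS, residual extraction, contrast maps
  smoothed at 1.5 mm FWHM.
* **Semipartial seed-to-voxel connectivity**
  (`semipartial_connectivity()`, `bandpass()`, `fisher_z()`,
  `intensity_exclude()`): band-pass 0.01–0.1 Hz, nuisance residualization,
  correlation with the variance *uniquely* explained by a seed (the seed is
  residualized against the competing seeds), Fisher z maps.
* **Winner-take-all parcellation** (`one_sample_tmap()`,
  `winner_take_all()`, `equalize_across_hemispheres()`): group one-sample
  T-maps per source, EC voxels assigned to the maximum-T source above
  T = 3.1, per-source counts equalized across hemispheres.
* **Transversal segmentation** (`segment_roi()`,
  `extract_segment_profile()`, `build_estimate_table()`): five equal-width
  subiculum bins and three 60° CA1 sectors per coronal slice, segment
  means averaged along the longitudinal axis.
* **Hierarchical statistics** (`rm_anova()`, `fdr_bh()`, `paired_t()`,
  `hierarchical_gradient_test()`, `content_bias_test()`): repeated-measures
  ANOVA cascade (overall seed × segment interaction per region → per-seed
  one-way ANOVAs → pairwise interactions), Benjamini-Hochberg FDR, and
  condition × region/segment content tests with post-hoc paired t-tests.

The statistical core is the classical within-subject ANOVA decomposition:
for an a × b within design with n subjects, each effect is tested against
its own subject × effect stratum, so the interaction has
F((a−1)(b−1), (a−1)(b−1)(n−1)) — e.g. F(12, 372) for 4 seeds × 5 segments
with n = 32 — with no sphericity correction by default
(Greenhouse–Geisser available as an option).

## Worked example

```r
library(ehconn)

cfg <- pipeline_config(phantom = phantom_config(
  n_subjects = 8, n_volumes_per_run = 130, rng_seed = 42))
res <- run_phantom_pipeline(cfg)

res$accuracy$accuracy          # hidden EC sublabels recovered
#> [1] 1

round(res$group_profiles$SUB, 2)   # group Fisher-z, proximal -> distal
#>         segment
#> measure     1    2    3    4    5
#>   EC_A35 0.75 0.64 0.50 0.33 0.19
#>   EC_A36 0.27 0.30 0.31 0.31 0.29
#>   EC_PHC 0.17 0.33 0.52 0.73 0.94
#>   EC_RSC 0.63 0.57 0.49 0.37 0.25

res$gradient_report$stage1
#>   region        F df_num df_den            p        p_adj significant
#> 1    SUB 426.5700     12     84 7.743208e-70 1.548642e-69        TRUE
#> 2    CA1 375.0089      6     42 8.152861e-35 8.152861e-35        TRUE

res$content$ec_report$posthoc[, c("unit", "t", "p_adj", "scene_gt_object")]
#>     unit         t       p_adj scene_gt_object
#> 1 EC_RSC 0.2655620 0.798227614           FALSE
#> 2 EC_PHC 4.9563069 0.006577835            TRUE
#> 3 EC_A35 1.8978580 0.199037965           FALSE
#> 4 EC_A36 0.7068359 0.670016396           FALSE
```

The winner-take-all parcellation recovers every hidden EC subregion; the
PHC-driven seed's connectivity rises toward the distal subiculum while the
A35- and RSC-driven seeds rise toward the proximal end (the imposed
opposing gradients), the seed × segment interaction is significant in both
target regions, and the scene > object bias appears only in the PHC-driven
EC seed — the topography the phantom encodes.

## The analysis workflow

The numbered scripts under `analysis/` run the full phantom experiment as
a narrative, writing tables and reports under `results/` (large
intermediates go to `scratch/`); run them from the repository root:

```sh
Rscript analysis/01_simulate_phantom.R       # phantom dataset + ROI sizes
Rscript analysis/02_entorhinal_parcellation.R  # seeds, counts, accuracy
Rscript analysis/03_transversal_profiles.R   # segment tables + figure
Rscript analysis/04_gradient_cascade.R       # hierarchical ANOVA cascade
Rscript analysis/05_content_bias.R           # scene/object content tests
Rscript analysis/06_type1_calibration.R      # null-phantom stage-1 rate
```

`run_pipeline("cfg.yaml", "out/")` runs everything from a single YAML
configuration and writes all NIfTI/TSV/JSON artifacts plus a provenance
record; reruns are bit-identical.

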