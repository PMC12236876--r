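# tendonload

Cumulative Achilles tendon load monitoring from three-channel plantar
force insoles.

Progressive tendon loading drives recovery in Achilles tendinopathy, but
the load that accumulates during ordinary daily life is invisible to the
clinic. Force-sensing insoles — three plantar pads (heel, midfoot,
forefoot) logged at 20 Hz — make weeks-long field monitoring possible.
This package implements the analysis chain for such recordings, for
researchers in wearable biomechanics and rehabilitation monitoring:

1. **Tendon load estimation** by ankle moment balance. Per sample,
   `M_PF = f_heel·r_heel + f_mid·r_mid + f_fore·r_fore` (signed sensor
   moment arms about the ankle, anterior positive) and
   `F_AT = max(M_PF, 0) / r_AT` with tendon moment arm `r_AT = 0.05` m,
   normalized by body weight (units ×BW).
2. **Cumulative load metrics** above two thresholds: *overall*
   (≥ 0.3 ×BW, the lowest-loading tendon exercise) and *high-level*
   (≥ 3.0 ×BW, ≈ peak walking load, so loading above it reflects dynamic
   activity). Loading time `T_load` and impulses are accumulated by
   rectangle-rule integration at the native rate; dividing each
   cumulative impulse by the total loading time yields the per-hour
   normalized loads `L_overall` and `L_high` (×BW per loading hour).
3. **Quality control**: rolling lower-envelope baseline-drift removal,
   erroneous-session screening (constant offsets, negative rails,
   too-short sessions) and a wear-protocol adherence check.
4. **Day-subsampling reliability**: mean absolute percent error and
   correlation of estimates from k = 1..6 monitoring days against the
   full dataset.
5. **Clinical correlation**: the 2 × 13 Pearson grid of both load
   measures against dynamometer capacity, dynamic function and survey
   measures, with the |r| ≥ 0.6 strong / 0.4–0.6 moderate / < 0.4 weak
   classification.
6. **A synthetic cohort generator** with closed-form ground truth —
   multi-day recordings with walking/running/jump bouts, rest and
   non-wear, injectable drift and erroneous-session artifacts, and
   clinical measures with a known linear-plus-noise dependence on each
   participant's latent activity volume — so the whole pipeline is
   testable end to end without any recorded data.

See the methods vignette (`vignettes/tendon-load-monitoring.Rmd`) for
the model details, generator design and numerical conventions.

## Worked example

A single-sample sanity check of the estimator — 600 N on the forefoot
(arm 0.11 m), tendon arm 0.05 m, body weight 660 N:

```r
library(tendonload)
rec <- insole_recording(f_heel = 0, f_mid = 0, f_fore = 600)
estimate_tendon_load(rec, sensor_geometry(), bw_n = 660)$load_bw
#> [1] 2
```

(66 N·m of plantarflexion moment / 0.05 m = 1320 N = 2.0 ×BW.)

A full synthetic run — 6 participants, 6 compressed days:

```r
cfg <- default_run_config(seed = 42, n_participants = 6, n_days = 6,
                          schedule_scale = 0.3, adherence_min_h = 0.3)
run <- run_pipeline(cfg)
summary(run)
#> Per-participant normalized cumulative Achilles tendon load
#>   L_overall (xBW per loading h): mean 1.240, SD 0.054, range 1.153-1.304
#>   L_high    (xBW per loading h): mean 0.110, SD 0.064, range 0.000-0.179
#>   total loading time (h): mean 2.3, range 2.1-2.4
#>   strong correlations: 13 of 26
```

`L_overall` near 1 ×BW per loading hour is a mean supra-threshold load
dominated by walking; `L_high` is small and highly variable because
high-level loading is concentrated in occasional running/jumping days —
one participant here never loads above 3 ×BW at all. That concentration
is exactly why few-day estimates of `L_high` are unreliable:

```r
head(as.data.frame(run$subsampling)[c("measure", "k", "mape_pct", "r")], 4)
#>     measure k  mape_pct         r
#> 1 l_overall 1  3.500426 0.6702684
#> 2    l_high 1 48.248684 0.6362058
#> 3 l_overall 2  1.960119 0.8222958
#> 4    l_high 2 24.267649 0.7988231
```

One day of data misestimates `l_high` by ~48 % on average but
`l_overall` by only ~3.5 %; both errors shrink as days accumulate.

A command-line wrapper over the same functions is installed at
`inst/scripts/tendonload-pipeline.R`
(`simulate | qc | summarize | subsample | correlate | all`).

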