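# axodyne

Quantification pipeline for in-vivo imaging studies of axon degeneration
in zebrafish sensory neurons, of the kind used to characterize
alpha-synuclein (aSyn) toxicity in Rohon-Beard cells. The package is for
researchers who need the full measurement chain — from time-lapse stacks
to group statistics — as tested, scriptable code rather than a stack of
manual ImageJ steps.

## What it computes

* **Mitochondrial transport from kymographs.** Time-lapse stacks
  (~1 Hz, 6 min, 50-µm axon segments) are collapsed along a traced axon
  path into a kymograph (rows = time, columns = arc length, band
  maximum normal to the trace). Tracks are extracted by decomposing the
  kymograph into a static component (per-column temporal median:
  stationary mitochondria) and a moving residual that is linked with
  velocity prediction, occlusion stitching, and identity-insensitive
  organelle grouping. Runs and pauses are segmented per frame; speed is
  the least-squares kymograph slope; a mitochondrion is *motile* only
  if a single run covers ≥ 2 µm at ≥ 0.1 µm/s. Summaries report percent
  motile, per-direction time fractions, percent retrograde distance and
  mean run speeds.
* **Mitochondrial morphometrics.** Otsu segmentation + connected
  components + second-moment ellipse axes give per-organelle
  length:width ratios and density per 100 µm.
* **5-point axonopathy staging.** Axon intensity profiles are scored
  1 (smooth) → 2 (mild beading) → 3 (severe beading / varicosities) →
  4 (partial fragmentation) → 5 (complete degeneration or soma death)
  by a configurable, scale-invariant threshold cascade.
* **Wallerian-degeneration kinetics.** From 30-min-sampled event
  series: lag (transection → ≥ 2 fragments), clearance (debris < 5%),
  synchrony, right-censoring, and the analytic half-interval
  quantization bias correction for mean lags.
* **Cohort statistics.** Survival percentages between 2 and 3 dpf
  (which may exceed 100% when new cells begin expressing the reporter),
  pooled-variance unpaired t-tests, one-way ANOVA, and a stepwise
  Newman–Keuls studentized-range post-test.
* **A seeded synthetic-data generator** (`simulate_*`) that emulates
  every experimental condition — WT, aSyn, aSyn+WldS, aSyn+PGC1a — with
  exact per-frame ground truth, driven by a shipped YAML of condition
  profiles encoding the published summary statistics as generator
  targets.

## Worked example

```r
library(axodyne)
profiles <- load_condition_profiles()

# simulate one WT transport movie and analyze it end to end
movie <- simulate_transport_movie(profiles$WT$transport, sim_config(),
                                  n_mito = 10, seed = 1)
kymo   <- build_kymograph(movie$stack, movie$trace)
tracks <- extract_tracks(kymo)
summarize_transport(tracks)

# the published 2-dpf aSyn stage distribution: 3, 12, 4 axons at stages 1-3
summarize_stages(stage_records(sprintf("axon%02d", 1:19), timepoint = 2,
                               stage = rep(1:3, c(3, 12, 4))))

# one embryo cohort under the aSyn profile, and a simulated transection
survival_percent(simulate_cohort(profiles$aSyn, n_cells = 20, seed = 1))
measure_wd(simulate_wd_timecourse(profiles$WT$timing, seed = 1))
```

This prints:

```
<kymograph> 360 frames x 249 arc bins | bin 0.2 um | dt 1 s
<transport_summary> 9 mitochondria, 2 motile (22.2%)
  % time  antero 49.1 | retro 4.1 | paused 46.8
  % distance retrograde 7.7
  run speed antero 0.533 um/s | retro 0.602 um/s
<stage_distribution> n = 19 at 2 dpf | mean stage 2.05 +/- 0.14
  counts (stage 1..5): 3 12 4 0 0
<survival_result> aSyn: 85.0% (20 -> 17 cells)
<wd_kinetics> lag 120 min | clearance 60 min | synchronous fragmentation
```

One 10-mitochondrion movie is a small sample — percent motile and the
time fractions of its two movers scatter widely around the WT targets
(27.4% motile, 41.25% time paused); the recovery checks below average
hundreds of organelles. The staging example reproduces the published
mean stage 2.05 ± 0.14 exactly from the printed frequency distribution;
the WD example shows a lag quantized to the 30-min sampling grid.

A full multi-condition run (simulation → kymograph → transport /
morphology / staging / cohort / WD → report JSON + manifest) is
available as `run_pipeline()`, with a thin command-line wrapper in
`inst/scripts/axodyne.R`.

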