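# knobmap

Multimodal motor mapping of the precentral hand knob in R: sulcus-aligned
TMS grid geometry, MEP amplitude/latency extraction and hotspot
localization, adaptive maximum-likelihood motor-threshold estimation, a
spatiotemporal hotspot *rostrality index*, movement-timing analysis of
paced force traces, and the cohort-level statistics that relate cortical
myelin content (quantitative-MRI R1 = 1/T1) to corticomotor representation
and behaviour — plus a calibrated synthetic-cohort generator that lets the
whole chain be validated end to end.

## Who this is for

TMS/EMG motor-mapping labs and methods developers who need a tested,
scriptable implementation of the sulcus-aligned mapping analysis:
map-based hotspot localization on a 5 x 7 grid that follows the precentral
gyrus, per-muscle excitability maps, and the composite rostrality measure
that captures where along the rostrocaudal axis a subject's corticomotor
output is best excited.

## The core quantities

* **Grid**: line 1 on the digitized gyrus-sulcus border, lines 2-5 offset
  anteriorly (5 mm), 7 targets per line at 5 mm arc spacing; per-site coil
  orientation perpendicular to the local line, pointing anteriorly.
* **MEP readouts**: peak-to-peak amplitude in the 10-40 ms window;
  onset latency by sustained threshold crossing (3 baseline SDs for
  0.5 ms); per-site mean amplitude maps; hotspot = site of maximal mean;
  shortest latency at the hotspot.
* **Rostrality index** per subject *i* and muscle, with min-max
  normalization across the cohort:

  index_i = norm(y_i) x norm(l_i),

  where y_i is the hotspot y-coordinate (anterior = larger) and l_i the
  shortest MEP latency; 0 = most posterior hotspot and shortest latency,
  1 = most anterior and longest. Hotspots on grid lines 1-2 define the
  caudal group, lines 3-5 the rostral group.
* **Timing precision**: force-trace peaks (threshold 0.6 V, prominence
  one third of the trace maximum, 0.4 s minimum separation), intermovement
  intervals within movement blocks, CV = SD/mean.
* **Statistics**: Pearson correlations with per-family Bonferroni
  adjustment, Welch group contrasts, paired ROI contrasts.

## Worked example

Simulate the default 24-subject study at full fidelity — raw EMG mapping
sessions (2 muscles x 35 sites x 20 trials) and paced force traces — and
push everything through extraction, indexing and statistics:

```r
library(knobmap)

cfg <- generator_config()        # calibrated defaults, seed 1
res <- run_pipeline(cfg, output_dir = "demo", emg_level = TRUE,
                    force_level = TRUE, quiet = TRUE)
res$cohort
#> <knob_cohort> 24 subjects (caudal 11, rostral 13), 20 with R1

b <- res$battery
b[b$set %in% c("rostrocaudal", "structure_function"),
  c("set", "x", "y", "r", "n", "p_adjusted")]
#>                  set             x              y      r  n p_adjusted
#> 1       rostrocaudal fdi_hotspot_y    fdi_latency  0.732 24   9.49e-05
#> 2       rostrocaudal adm_hotspot_y    adm_latency  0.564 24   8.24e-03
#> 3 structure_function       r1_mean fdi_rostrality  0.846 20   1.61e-05
#> 4 structure_function       r1_mean adm_rostrality  0.648 20   1.20e-02
#> 5 structure_function       r1_mean     bold_index  0.851 20   1.20e-05
#> 6 structure_function       r1_mean    bold_little  0.825 20   4.56e-05
#> 7 structure_function       r1_mean       cv_index -0.596 20   3.36e-02
#> 8 structure_function       r1_mean      cv_little -0.416 20   4.11e-01
```

Reading the output: hotspot y-coordinates and shortest MEP latencies were
*extracted from the raw simulated EMG*, and correlate at r = 0.73 — more
anterior hotspots come with longer corticomotor latencies. Whole-knob R1
correlates positively with the rostrality index and task-related BOLD and
negatively with the intermovement CV (the CV was recovered from force
traces by peak detection). At n = 20 a single cohort's sample correlation
has an SE of ~0.12, which is why single-run values scatter around the
generator's calibration targets; `demo/summary.txt` prints the comparison:

```
knobmap pipeline summary (n = 24, seed = 1)
  r1_vs_fdi_rostrality   target +0.699  recovered +0.846
  y_vs_latency_fdi       target +0.697  recovered +0.732
  r1_vs_bold_little      target +0.748  recovered +0.825
  r1_vs_cv_little        target -0.684  recovered -0.416
  (single-cohort sample correlations; at n ~ 20 their SE is ~0.12)
```

The paired ROI contrasts recover the structural gradient — higher R1
(myelin) caudally, thicker cortex rostrally:

```r
res$roi_contrasts[, c("measure", "mean_caudal", "mean_rostral", "statistic", "dof", "p")]
#>     measure mean_caudal mean_rostral statistic dof        p
#> 1        r1     790.267      754.215      3.68  19 1.59e-03
#> 2 thickness       2.522        2.726     -5.25  23 2.54e-05
#> 3 curvature       0.025       -0.079     28.48  23 1.94e-19
#> 4      bold       1.534        1.256      4.21  23 3.34e-04
```

Lower-level entry points: `build_grid()` / `arc_length_resample()` for the
geometry, `analyze_emg_session()` / `find_hotspot()` /
`estimate_rmt_pest()` for the electrophysiology, `rostrality_index()`,
`detect_peaks()` / `interval_cv()` for timing, and
`run_correlation_battery()` for the statistics. The methods vignette
(`vignettes/knobmap-methods.Rmd`) documents the models, calibration and
numerical choices.

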