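# recoilr

Quantitative analysis of cortical tension and Myosin distribution in
epithelia, for researchers measuring tissue mechanics with laser ablation and
fluorescence microscopy.

When a single cell–cell interface is severed with a pulsed UV laser, the
released actomyosin tension drives the two flanking tricellular vertices
apart. `recoilr` turns manually tracked vertex positions into the two
standard mechanical readouts:

- **retraction velocity** — the change in vertex-to-vertex distance between
  the images immediately before and after ablation, divided by the time
  elapsed; proportional to the tension released;
- **Kelvin–Voigt fit** — the recoil increment is modelled as the damped
  recoil of an elastic fibre (spring of elasticity *E* and dashpot of
  viscosity *μ* in parallel),

  ΔL(t) = D (1 − e^(−t/τ)),  τ = μ/E,

  where *D* is the asymptotic recoil amplitude and the relaxation time τ is
  the viscosity-to-elasticity ratio of the tissue (*μ* and *E* are not
  separately identifiable from recoil data).

Around that core the package provides the accompanying image and morphometry
statistics: maximum-intensity projection and bilinear linescan extraction
with the **heterogeneity** statistic (sd/mean of the intensities along a
line, high for punctate junctional Myosin), **clone/control ratio**
morphometry for mosaic tissues (per-follicle ratio of clone-cell to
control-cell means), and the group comparisons used with these readouts
(Mann–Whitney U with exact small-sample p-values, pooled-variance Student's
t, one-way ANOVA, percent change, mean ± s.d. summaries).

A synthetic-data generator produces vertex tracks, epithelium z-stacks and
clone measurement ensembles with known ground truth, so the whole pipeline
is testable without microscopy data.

## Worked example

Fit one simulated junction, then compare two conditions the way an ablation
experiment is analysed (17 control junctions vs 12 junctions with a
programmed 49% lower mean recoil amplitude):

```r
library(recoilr)

tr <- simulate_recoil_track(recoil_sim_params(L0 = 3, D = 1.2, tau = 10,
                                              noise_sd = 0.05, seed = 11))
analyze_track(tr)
#> Track 'sim': retraction velocity 0.09954 um/s
#> Kelvin-Voigt recoil fit
#>   D   = 1.149 um (asymptotic recoil amplitude)
#>   tau = 8.506 s  (relaxation time, viscosity/elasticity)
#>   rss = 0.01997 um^2 on 9 post-ablation frames (nlsLM)

ctl <- simulate_condition_ensemble(ensemble_spec(n_replicates = 17, seed = 1))
ko  <- simulate_condition_ensemble(ensemble_spec(n_replicates = 12,
                                                 D_mean = 0.51 * 1.2, seed = 2))
v_ctl <- analyze_tracks(ctl)$velocity_um_s
v_ko  <- analyze_tracks(ko)$velocity_um_s
compare_groups(v_ctl, v_ko, labels = c("control", "knockdown"))
#> Comparison: control vs knockdown (Mann-Whitney U)
#>   control      mean 0.1029 +/- 0.02746 s.d. (n = 17)
#>   knockdown    mean 0.06305 +/- 0.03239 s.d. (n = 12)
#>   change: -38.8%, statistic = 35, p = 0.003233 **
```

The single-track fit recovers the generating parameters (D = 1.2 µm,
τ = 10 s) up to tracking noise; the ensemble comparison detects the
programmed velocity drop (here −38.8% observed for a −49% programmed effect
at these sample sizes) with a significant Mann–Whitney p-value.

Linescan and morphometry statistics work on plain vectors or on images:

```r
linescan_stats(c(80, 120, 95, 210, 70, 150))
#> Linescan stats: mean 120.8, sd 52.38, heterogeneity 0.4335 (n = 6)

clone_ratio(clone_set("follicle1", c(2.9, 3.1, 2.7), c(5.0, 4.8, 5.3)))
#> Unit 'follicle1': clone/control width ratio = 0.5762 (means 2.9 / 5.033)
```

`run_pipeline()` (or the wrapper script `inst/scripts/recoil-pipeline.R`)
ties the stages into a reproducible run that writes per-track results,
comparison reports and a manifest (configuration, seed, versions) to disk;
identical configuration and seed give identical outputs.

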