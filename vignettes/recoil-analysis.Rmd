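---
title: "Measuring cortical tension from laser-ablation recoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cortical tension from laser-ablation recoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoilr)
```

## The physical model

Epithelial cell junctions are under actomyosin tension. Severing one
interface with a pulsed laser releases that tension and the two tricellular
vertices flanking the cut recoil apart. `recoilr` models the recoil as the
damped relaxation of a Kelvin–Voigt element — a spring (tissue elasticity
$E$) and a dashpot (viscosity $\mu$) in parallel:

$$\Delta L(t) = D\,\bigl(1 - e^{-t/\tau}\bigr), \qquad \tau = \mu / E,$$

where $\Delta L(t)$ is the increase of the vertex-to-vertex distance $t$
seconds after ablation, $D$ is the asymptotic recoil amplitude, and the
relaxation time $\tau$ is the viscosity-to-elasticity ratio. Two readouts
summarise each experiment:

* the **initial retraction velocity** — the length change between the last
  pre-ablation and first post-ablation image divided by the elapsed time —
  scales with the tension released and is the primary tension readout;
* the **fitted $(D, \tau)$** characterise the viscoelastic response;
  $\mu$ and $E$ appear only through their ratio and are deliberately never
  reported separately, because recoil data cannot identify them
  individually.

Assumptions worth keeping in mind: a single junction is treated as an
isolated fibre (no mechanical coupling to neighbouring junctions), tension
is constant over the ~36 s observation window, and the tracked vertices are
the true endpoints of the severed interface.

## Fitting choices

**Increment, not absolute length.** The model curve passes through zero at
$t = 0$ while the physical interface has nonzero length at ablation. The
package therefore fits the recoil *increment*
$\Delta L(t) = L(t) - L_\mathrm{ref}$, which preserves the model's
functional form while matching the observable. $L_\mathrm{ref}$ is the
length at the last pre-ablation frame by default; with several pre-ablation
frames their mean can be used instead (`L_ref = "mean"`), which averages
tracking noise at the cost of assuming a static pre-ablation length.

**Time origin.** Acquisitions run at one frame every `frame_interval`
seconds (default 4 s) before and after ablation; the ablation instant within
the inter-frame gap is unobserved. We place $t = 0$ at the last pre-ablation
frame, so the first post-ablation point sits at $t = \Delta t$, and fit only
post-ablation frames. The $(0, 0)$ anchor can optionally be included as a
data point (`include_t0 = TRUE`); it is excluded by default because the
anchor is a convention, not a measurement.

**Optimisation.** Bounded Levenberg–Marquardt least squares with
$D \ge 0$ and $\tau \in [\Delta t/10,\; 10\,T]$ ($T$ = last post-ablation
time): relaxation times far below the frame interval or far beyond the
observation window are not measurable from the data and the bounds keep the
optimiser out of those regimes. Starting values are $D_0 = \Delta L$ at the
final frame and $\tau_0$ = the earliest time at which $\Delta L$ reaches
$(1 - 1/e)D_0$ (linear interpolation). The optimiser's solution is then
refined by Newton steps on the gradient of the $\tau$-profiled residual sum
of squares (the optimal $D$ for fixed $\tau$ is a linear projection and is
concentrated out analytically). This refinement matters numerically: near
the optimum the rss surface is too flat in double precision to compare
candidate parameters, but the profiled gradient is linear there, so its
zero pins $\tau$ to machine precision and the fit becomes an effectively
continuous function of the data — rigid motions of the coordinate system
change the fit by less than one part in $10^9$. If the gradient-based fit
fails outright, an exhaustive $200 \times 200$ grid search over the same
bounds (followed by a bounded local polish) takes over and the `method`
field records the fallback.

**Degenerate inputs.** A series with no net recoil ($D_0 \le 0$) is
reported with `converged = FALSE` and diagnostics rather than an error, and
ensemble summaries count non-converged fits instead of silently dropping
them. Unweighted least squares is used throughout: no per-frame uncertainty
model is available for manually tracked vertices.

**Dispersion conventions.** Whether published "τ ± x" intervals are s.d. or
s.e.m. of per-junction estimates is often ambiguous, so pipeline comparison
reports include the mean, s.d., s.e.m. and median of fitted $\tau$ per
condition.

## The synthetic-data generator

Every stage is validated against generated data with known ground truth.
The generator's defaults describe a stage-14 embryonic-epidermis ablation
experiment:

| parameter | default | rationale |
|---|---|---|
| `frame_interval` | 4 s | acquisition rate of the reference experiments |
| `n_post` | 9 frames | 36 s of post-ablation tracking |
| `L0` | 3 µm | typical junction length in the embryonic epidermis |
| `D` | 1.2 µm | gives initial velocities ≈ 0.1 µm/s at τ = 10 s |
| `tau` | 10 s | control-regime relaxation time |
| `noise_sd` | 0.05 µm | manual vertex-tracking jitter (≈ half a pixel) |
| CVs (L0, D, τ) | 0.2, 0.25, 0.1 | inter-embryo spread; τ CV matches a 10 ± 1 s regime |

Inter-replicate variability is lognormal, parameterised by arithmetic mean
and CV — lognormality keeps all physical parameters positive and the CV
parameterisation is directly interpretable. Tracking noise is isotropic
Gaussian per vertex coordinate per frame, uncorrelated across frames. Each
generator takes a single integer seed; ensembles derive per-replicate seeds
by a fixed prime stride, so every replicate is individually reproducible,
and generators save and restore the session RNG state.

The epithelium generator builds a Voronoi-like lattice (cell seeds on a
jittered square grid, default jitter 0.2 cell diameters; pixels nearly
equidistant to their two nearest seeds form the junction mask). Punctate
Myosin is emulated by multiplying the junction intensity by
$1 + p\,\sin(2\pi s / \lambda)$ with $s$ a spatial phase advancing along
the junctions and $\lambda$ = 1 µm, roughly the spacing of bright Myosin
puncta; $p = 0$ gives uniform junctions. With zero jitter the lattice is
rectangular and axis-aligned junction rows allow exact-zero heterogeneity
checks.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: mechanical coupling between neighbouring junctions
(each track is independent), systematic tracking bias (only unbiased
jitter), photobleaching, out-of-focus background gradients, curved
junctions, and any relationship between junction geometry and Myosin level.
Recovery results on synthetic data bound what the estimators can do under
the stated noise model, not under every imaging condition.

## Linescan and morphometry conventions

Heterogeneity is sd/mean of the intensities sampled along a line. The
standard deviation uses the sample ($n-1$) denominator by default, exposed
as `sd_denominator` since published definitions rarely state the choice;
tests pin the default. Linescans are taken on the maximum-intensity
projection (default: all slices; typically 5 apical slices of 0.5 µm),
sampled by bilinear interpolation at one pixel of arclength per step, with
a line width of one sample — optional perpendicular averaging is
deliberately absent because a plain drawn line is the field's convention.
Embryos, not linescans, are the unit of analysis: several linescans per
embryo are averaged into one (mean, heterogeneity) pair, and the count is
recorded.

Clone morphometry reports, per follicle or segment, the ratio of the
clone-cell mean to the control-cell mean. Ratio of means rather than mean
of per-cell ratios: the design pairs *groups* of cells (labelled cells vs
facing control cells), group sizes are unequal, and the ratio of means is
the estimand that a common calibration factor cancels out of. Per-unit
ratios — not a pooled ratio — are the statistical observations, matching
designs in which follicles are the replicates.

## Statistical tests

The Mann–Whitney U statistic is computed from midranks. For tie-free data
with combined $n \le 14$ the two-sided p-value is exact (doubled one-sided
tail of the permutation null, capped at 1); the threshold keeps exact
enumeration instant at interactive scale while covering the sample sizes at
which the normal approximation is least reliable. Beyond it, the normal
approximation with tie correction and continuity correction is used.
Student's t is the pooled-variance two-sample version; one-way ANOVA is the
standard between/within decomposition. Percent change is defined on group
means, matching how condition-level effects are reported. No
multiple-testing correction is applied (none is conventional for these
figure-level comparisons); comparison reports state the test used, and
significance stars follow the common thresholds (\*, \*\*, \*\*\*, \*\*\*\*
for $p \le$ 0.05, 0.01, 0.001, 0.0001).

Degenerate cases are flagged rather than erroring: identical samples give
$p = 1$; zero pooled variance with unequal means is reported with a
degeneracy flag.

## Numerical and I/O notes

* Uniform frame spacing is validated to a relative tolerance of $10^{-6}$;
  vertex coordinates must be finite.
* TIFF stacks are written as 32-bit float pages scaled into [0, 1], with the
  scale factor, pixel size and z-step in a sidecar JSON (the TIFF writer
  cannot embed resolution tags); round trips are exact to float32
  precision (~$10^{-7}$ relative). Reading resolves pixel size as sidecar
  → explicit override → TIFF resolution tag, and fails loudly if none is
  present.
* Pipeline outputs carry a schema label and the seed; the manifest echoes
  the full configuration so a run is reproducible from its output directory
  alone.

## Validation problem sizes

The test suite validates exact recovery on noiseless tracks ($D \in \{0.5,
1, 2\}$ µm $\times$ $\tau \in \{5, 10, 20\}$ s), optimiser-vs-grid-oracle
dominance on 50 seeded noisy tracks, median-$\tau$ recovery within 15% from
200 noisy tracks per regime ($\tau^* = 10$ and 12 s), end-to-end detection
of a programmed 49% velocity drop across 100 repetitions of a 17-vs-12
junction experiment, heterogeneity ordering (punctate > uniform) across 100
seeded epithelium pairs, exact Mann–Whitney agreement with brute-force
enumeration and a 2000-simulation null calibration, and recovery of a 0.6
constriction factor over 500 synthetic cohorts. These sizes give stable
Monte-Carlo estimates while keeping the full suite fast enough to run on
every change.

## Limitations

Single-exponential Kelvin–Voigt recoil is the simplest viscoelastic model;
power-law or multi-mode rheologies are out of scope, as are automated vertex
tracking, junction segmentation, automatic line placement, background
subtraction and bleaching correction. Tracks, linescans endpoints and
per-cell measurements are inputs; producing them from raw movies remains an
interactive step.
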