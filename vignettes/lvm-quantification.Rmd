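---
title: "Quantifying left-ventricular mass from 2D echocardiographic delineations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular mass from 2D echocardiographic delineations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echolvm)
```

## The problem

Left-ventricular mass (LVM) is the product of myocardial volume and
myocardial density (1.05 g/ml): the volume enclosed by the epicardium at
end-diastole minus the volume enclosed by the endocardium,

$$\mathrm{LVM} = 1.05 \cdot (\mathrm{EDV_{EPI}} - \mathrm{EDV_{ENDO}}).$$

Every echocardiographic method is a different geometric model for those two
volumes. The linear (1D) cube formula assumes a symmetric prolate ventricle
whose dimensions are captured by three caliper readings in one parasternal
long-axis line; area--length and the truncated ellipsoid replace the wall
readings with a traced short-axis (SAX) area pair but still assume an
idealised solid of revolution; the fully delineated biplane method needs
the epicardial border in the apical views, which is the hardest interface
to see. The disc-expansion method implemented here keeps the part of the
standard examination that is robust --- the endocardial biplane
delineation and a single SAX trace --- and builds the epicardial volume
from them.

## The disc-expansion algorithm

Given an endocardial disc stack (semi-axes $a_i$ from the 4-chamber view
and $b_i$ from the 2-chamber view, $n$ discs of common height $h$) and a
SAX trace with epicardial area $A_1$ and endocardial area $A_2$:

1. **Mean wall thickness** $t = \sqrt{A_1/\pi} - \sqrt{A_2/\pi}$, the
   difference of equivalent-circle radii. The whole circumference
   contributes to each area, so local tracing errors average out.
2. **Endocardial volume** $\mathrm{EDV_{ENDO}} = \sum_i \pi a_i b_i h$,
   optionally calibrated by a factor $k$.
3. **Epicardial volume** by expanding every disc elementwise,
   $a_i \to a_i + t$, $b_i \to b_i + t$, plus an apical cap
   $\tfrac{2}{3}\pi\, a_{\mathrm{apex}} b_{\mathrm{apex}}\, t$ — a half
   prolate ellipsoid of height exactly $t$ over the expanded apical disc,
   chosen because the epicardium extends $t$ beyond the endocardial apex
   and the cap must vanish with $t$.
4. **Mass** as the density-weighted difference. By construction
   $\mathrm{LVM}/1.05 + \mathrm{EDV_{ENDO}} = \mathrm{EDV_{EPI}}$ exactly,
   and the mass is strictly increasing in $t$ and in $k$ and scales as
   $s^3$ under geometric similarity — these identities are enforced as
   property tests.

Design choices where the method description left room:

* **$k$ acts before expansion** (so the mass depends on $k$): the
  calibration belongs to the endocardial volume reconstruction, upstream of
  the wall model. Default `k = 1` in `volume_scale` mode, in which every
  semi-axis is multiplied by $\sqrt{k}$ and the biplane volume scales
  exactly by $k$. The published CMR calibration constant for this factor is
  not reproduced here; `k_from_volumes()` documents the cohort-mean preset
  197/151 ≈ 1.30 and `radial_scale` is provided as the alternative reading.
* **Elementwise semi-axis expansion** (elliptical discs stay elliptical):
  the only reading consistent with expanding "each unique disc"; expanding
  an equivalent circular radius would discard the per-view asymmetry the
  biplane delineation was chosen to preserve.
* **Density 1.05 g/ml**, configurable (`novel_config(density_g_per_ml=)`),
  since some CMR laboratories use 1.055.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | 1.0 | — | volume calibration; never silently non-unity |
| `n_discs` | 30 | — | disc count of the biplane sum; some software uses 20 |
| `density_g_per_ml` | 1.05 | g/ml | myocardial density |
| `sax level` | `"chordae"` | — | recorded metadata; no level correction applied |
| `sax_level_fraction` (phantom) | 0.4 | fraction of length from base | geometric stand-in for the chordae level, between the mitral (~0.2) and mid-papillary (~0.5) planes |

Disc sampling uses the **midpoint rule**: semi-axis $i$ is the half chord
at level $(i - \tfrac12)/n$ of each view's own long-axis length, and the
disc height is the effective length $\max(L_{4CH}, L_{2CH})/n$. Midpoint
sampling is second-order accurate; the test suite verifies the
$O(1/n^2)$ error decay on the hemi-ellipsoid phantom and a relative error
below 0.5% at $n = 30$.

## The phantom simulator

`phantom_spec()` defines analytic ventricles with closed-form truth:

* **hemi_ellipsoid** (default: cavity length 8 cm, short semi-axes 2.5 cm,
  wall 1 cm — a normal-sized adult LV): cavity
  $\tfrac{2}{3}\pi b c L$, myocardium
  $\tfrac{2}{3}\pi[(b+t)(c+t)(L+t) - bcL]$.
* **cylinder_flat_cap**: cavity $\pi b c L$; shell plus flat apical cap.
  Deliberately far from every method's assumed geometry — useful for
  stressing model error.
* **septal_bulge**: a circular cylinder with a cosine-tapered epicardial
  thickening $\Delta(z,\theta) = E \cos^2\!\frac{\pi\theta}{2\alpha}
  \cos^2\!\frac{\pi(z-z_0)}{2w}$ confined to the septal (4CH) side and
  centred on the SAX plane. The bulge volume integrates in closed form,
  $(r+t)E\alpha w + \tfrac{E^2}{2}\cdot\tfrac{3\alpha}{4}\cdot\tfrac{3w}{4}$.
  The bulge is attached to the cylinder rather than the hemi-ellipsoid
  because on an ellipsoidal shell the cross term
  $\int \sqrt{1-(z/A)^2}\cos^2(\cdot)\,dz$ has no elementary closed form,
  and an exactly known truth matters more here than anatomical polish.

`render_measurements()` emits every method input noiselessly and
consistently with the geometry (true cross-sections, true meridional
contours, true in-plane wall thicknesses; the bulge, when intersected,
adds to IVS only). On the septal-bulge phantom the caliper IVS reads the
full local thickening while the SAX area dilutes it around the
circumference — reproducing the focal-hypertrophy failure mode of linear
methods, and tested as a deterministic ordering
$|\mathrm{NOVEL}-\mathrm{truth}| < |\mathrm{DEV}-\mathrm{truth}|$.

Note one deliberate subtlety: for the hemi-ellipsoid the epicardial
surface is the ellipsoid with every semi-axis enlarged by `wall_cm`, which
is **not** a constant-thickness offset surface; the rendered in-plane wall
thickness at the SAX plane (≈ 0.98 cm for the default) therefore differs
slightly from `wall_cm`. The phantom reports what a sonographer would
measure, not the nominal parameter.

What a green phantom test does establish: the arithmetic of each method,
the disc-slicing machinery, and the relative model error of the methods on
known geometries. What it does not establish: performance on real
ventricles (trabeculation, foreshortening, view-dependent image quality,
correlated sonographer error are all absent).

## Measurement noise

`noise_model()` applies zero-mean Gaussian noise: additive on each caliper
reading, relative on each traced SAX area, and one common relative factor
per apical view on all chord widths (tracing error is strongly correlated
along one traced border; independent per-disc noise would self-average
over 30 discs and flatter the biplane methods). Distinct measurements are
independent. Draws violating a type invariant (negative length,
$A_1 < A_2$) are redrawn, so perturbed records are always valid.

**A deliberate red test.** The acceptance suite contains a Monte-Carlo
criterion asserting that, under *equal relative* noise on every input
(IVS, LVID, PWT, $A_1$, $A_2$, chords — sd $\rho = 0.10$, the magnitude of
the 11-vs-10 mm example), the cube-formula CV exceeds the disc-expansion
CV. With *independent* equal-relative area noise this is false, and the
test fails by construction of the statistic, not by a bug: the wall
thickness $t = \sqrt{A_1/\pi} - \sqrt{A_2/\pi}$ is a small difference of
two large radii, so its sd is
$\tfrac{\rho}{2}\sqrt{R_1^2 + R_2^2} \approx 2\rho$ (at $R_1 \approx 3.3$,
$R_2 \approx 2.3$ cm) — about twice $t$ itself per unit $\rho$ — and the
mass sensitivity $(\partial V/\partial t)(t/V) \approx 1.2$ amplifies it
to ≈ 2.5ρ, against ≈ 1.9ρ for the cube formula (Monte-Carlo: ≈ 26% vs
≈ 19% at $\rho = 0.10$; the ratio is invariant in $\rho$). The advantage
claimed for area-derived wall thickness rests on *circumferential
averaging*: each boundary point carries localisation error $\rho$, but a
traced border averages roughly $n_\mathrm{eff}$ independent segments, so
the area's relative error is $2\rho/\sqrt{n_\mathrm{eff}}$, not $\rho$.
Under that physically grounded model (with $n_\mathrm{eff} = 20$, a
contour of ~20 independent speckle-scale segments) the ordering holds
comfortably, and a companion property test in `test-novel.R` verifies it.
The acceptance criterion is left failing rather than reinterpreted,
because "equal relative input noise" is its stated world.

## Statistics

* **Bland–Altman**: bias, $\pm 1.96\,\mathrm{SD}$ limits of agreement (the
  conventional multiplier, not a small-sample $t$ quantile), proportional
  bias as the slope of differences on pair means, paired-$t$ p-value. All
  checked against direct textbook computation to 1e-10.
* **CV**: the denominator convention is ambiguous in the reproducibility
  literature, so both are offered and the choice is recorded in the
  output: `sd_diff` (default; SD of paired differences over the grand
  mean, the convention that pairs naturally with limits of agreement) and
  `within_subject` ($\div\sqrt{2}$).
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures — the conservative form appropriate for test–retest data. The
  implementation uses the explicit sum-of-squares decomposition and is
  tested against an independent `stats::aov` route. Zero total variance
  returns a flagged undefined result rather than a number.
* **Hypertrophy classification**: indexed mass ($\mathrm{LVM/BSA}$)
  against an editable cutoff table stratified by method group, sex and
  age (volumetric methods use age-stratified CMR-derived thresholds of
  92/91 and 78/79 g/m²; TE/A-L use 103/89; the cube formula 116/96).
  Every boundary is exercised at ±0.1 g/m² in the acceptance suite. A
  companion indexed-EDV table supports dilatation grouping.

## Numerical choices and frozen tolerances

* Disc-expansion recovery on the default hemi-ellipsoid phantom: measured
  once at −0.8% (end-to-end, SAX-derived $t$) and +1.7% (with the nominal
  wall thickness); tolerance frozen at **2%** and never revisited.
* Area–length vs truncated ellipsoid on the same phantom: the two models
  genuinely disagree by ~10% on a hemi-ellipsoid (they are different
  solids); tolerance frozen at **12%**.
* The cube formula's additive 0.6 g breaks exact $s^3$ scale invariance of
  its relative error; the scale-invariance property test removes the
  constant first.
* Truncation below the equator ($d > a$) in the truncated ellipsoid is
  accepted with a warning rather than forbidden.
* All lengths are cm, areas cm², volumes ml, masses g; record files may
  declare mm/mm² and are converted on read.

## Limitations

Inputs are assumed to be already-extracted delineations; there is no image
processing, no foreshortening detection, and no contour smoothing. The
wall thickness comes from a single SAX level, so distal thinning
(aneurysm) or basal septal hypertrophy outside that plane biases the mass,
as it does for every single-plane method. The noise model is a documented
stand-in for sonographer error, not an estimate of it. The phantom family
is smooth and convex; real ventricles are neither.
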