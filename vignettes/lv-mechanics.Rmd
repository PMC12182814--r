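---
title: "Regional LV mechanics, dyssynchrony, and phenotype discovery with lvmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional LV mechanics, dyssynchrony, and phenotype discovery with lvmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmech)
```

This vignette is the package's account of its models and the design
decisions behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic data do and do not
emulate, and where the numerical corners are.

## 1. The contracting-annulus phantom

Validating a strain pipeline requires data whose strain is known exactly.
The phantom is the simplest object with that property that still exercises
every code path: a 2-D annulus (endocardial radius $r_{endo,0}$, epicardial
radius $r_{epi,0}$ at end-diastole) that contracts incompressibly. Each
angular sector $s$ carries a contraction fraction $c_s \in [0,1)$ and an
activation delay $\delta_s$; the endocardial radius follows

$$R_{endo}(t) = r_{endo,0}\,\bigl(1 - c_s\, w(t - \delta_s)\bigr), \qquad
  w(u) = \sin^2\!\bigl(\pi\, (u \bmod T) / T\bigr),$$

with $T$ the cycle length. Conservation of annular area maps a material
point at ED radius $R$ to $r(R,t) = \sqrt{R^2 + R_{endo}(t)^2 -
r_{endo,0}^2}$, so the radial engineering strain is **exactly** $\varepsilon_r(R,t)
= R/r(R,t) - 1$ and the Eulerian radial velocity collapses to $v(\rho,t) =
R_{endo}\dot R_{endo}/\rho$. The $\sin^2$ waveform was chosen because it is
smooth, returns strain to zero at end-cycle (no drift by construction), and
makes the true time-to-peak closed-form: $TTP_s = (T/2 + \delta_s) \bmod T$.

Sector parameters are blended linearly over ±5° at sector boundaries.
Without blending the velocity field is discontinuous in angle and the
least-squares deformation gradients at boundary pixels are polluted; 5° is
about two pixels of arc at the default geometry, the smallest width that
restores differentiability without eroding the sector plateaus.

Default geometry — 128×128 grid at 0.5 mm, 40 frames of 25 ms (T = 1 s,
heart rate 60 bpm), $r_{endo,0}$ = 20 mm, $r_{epi,0}$ = 28 mm, $c$ = 0.25 —
gives an end-diastolic wall of 8 mm and a peak mid-wall radial strain of
19.85%, all values in the physiological range for an adult short-axis
mid-ventricular slice. Inside the cavity (where there is no tissue) the
velocity ramps linearly to zero at the center; this keeps interpolation
near the endocardial border well behaved and has no analog in tissue.

## 2. The strain engine

**Tracking.** ED-mask pixels are integrated with explicit (forward) Euler,
$x_{k+1} = x_k + v(x_k, t_k)\,\Delta t$, sampling velocities bilinearly.
Euler was chosen over Runge-Kutta deliberately: at the default temporal
resolution the tracking error contributes well under 0.1 percentage points
to segmental peak strain (the convergence test halves spacing and frame
duration and verifies the error shrinks), and a first-order scheme keeps
the velocity-sampling contract trivial — one interpolation per frame, no
mid-step samples outside the acquisition grid. Velocities undefined on a
pixel (allowed in real data where estimates exist only on the myocardium)
are filled from the nearest defined pixels by iterative dilation before
interpolation. Trajectories that exit the image are flagged, excluded from
segment averages, and counted in a message.

**Strain.** Per pixel, the deformation gradient $F_k$ is fitted by least
squares over the tracked displacements of the pixel's ED neighborhood (all
mask pixels within a 2-pixel radius, ≥ 3 required; singular neighborhoods
are flagged and excluded). Strain is the stretch-based engineering measure
$\sqrt{e^\top C e} - 1$ with $C = F^\top F$, evaluated along the ED radial
and tangential unit directions about the cavity centroid. The engineering
convention (rather than Green-Lagrange $\tfrac12(e^\top C e - 1)$) was
chosen because radial thickening of 30–80% is the working range of this
application and the engineering measure is what the clinical literature
reports at those magnitudes. Both strains are exactly zero for rigid
motions, which the rotation test asserts.

**Segmentation.** AHA segments are equal angular sectors about the
centroid — 6 × 60° (basal, mid), 4 × 90° (apical) — swept counterclockwise
from an explicit anterior reference angle, with the first sector boundary
at the reference. Automatic detection of the anterior RV insertion is out
of scope; the reference is an input, and the phantom's convention
(reference "up") is the default. The apex cap (segment 17) is never
emitted. Segmental curves are means over valid pixels, re-zeroed at frame
0 (ED is the reference configuration); strain rate is the centered
difference of the segmental curve (one-sided at the ends), in 1/s.

**Summaries.** Peak radial strain is the curve maximum × 100; time-to-peak
is the argmax × frame duration with **ties broken to the earliest frame**
(a deliberate, documented rule — flat-topped curves otherwise make TTP
ill-defined). The slice's global radial strain is, by default, the peak of
the pixel-count-weighted mean segmental curve; whether "global" means that
or the mean of segmental peaks is genuinely ambiguous in practice, so the
alternative is exposed as `global = "mean_of_peaks"`.

## 3. Dyssynchrony statistics

All four statistics are computed from the radial channel only, over the
full cycle (no systolic gating), separately per slice.

* **sdTTP** uses the population SD (divisor $n$): the segments of a slice
  are the complete population of interest, not a sample.
* **maxTTP** is the maximum segmental TTP (not the maximum pairwise
  difference — the other reading of "maximum time to peak"; the pairwise
  spread is recoverable from the TTP vector, so nothing is lost).
* **SRCC** finds, per unordered segment pair, the lag maximizing the
  normalized circular cross-correlation of zero-mean strain-rate curves,
  searching |lag| ≤ half a cycle so lags stay identifiable on a periodic
  signal; ties prefer the smaller |lag|, then the positive one. The default
  aggregation is the **mean** absolute pairwise lag (in ms); the maximum is
  available via `srcc_agg = "max"`. The mean was preferred because a single
  delayed segment then contributes proportionally ($\delta/3$ for one
  delayed segment among six) rather than saturating the statistic.
* **RURE** Fourier-transforms the segmental strains around the
  circumference at each frame and forms $\sum_t A_0 / \sum_t (A_0 + A_1)$
  from the order-0 and order-1 magnitudes. It is 1 iff the order-1
  component vanishes at every contributing frame (uniform contraction) and
  0 for a pure opposing-wall pattern. Magnitudes, not powers, keep the
  ratio scale-free in amplitude units; the time-summed form weights frames
  by contraction amplitude, which suppresses the noise-dominated
  near-diastolic frames — a per-frame-averaged variant is available
  (`rure_variant = "framewise"`). Apical slices use their 4 segments
  directly; the order-1 coefficient is still well defined.

Degenerate inputs degrade softly: flat curves give `NA` TTP, and
`slice_metrics()` returns an all-`NA` record rather than erroring, so a
single failed slice does not abort a cohort run.

## 4. The cohort simulator

The simulator emulates the *feature distributions and outcome structure* of
a 198-patient rTOF cohort, not its images: four phenotypes of sizes
39/29/56/74 with Gaussian templates over the 25 clustering features,
anchored so the phenotype mixture approximately reproduces published
whole-cohort reference means (septal strains depressed overall, lateral
strains elevated, per-slice dyssynchrony moderate), and contrasts between
phenotypes following the clinical pattern: (1) severe septal dysfunction
with marked dyssynchrony, (2) globally reduced strain without
dyssynchrony, (3) preserved strain and synchrony, (4) preserved strain
with mild dyssynchrony. The per-phenotype means and SDs are synthetic
approximations — the within-phenotype SDs are set below the whole-cohort
spread so the mixture reproduces it — and are fixed constants in the
package, not fitted quantities.

Features are drawn independently per feature (a covariance hook exists but
defaults to diagonal: only means ± SDs are available to parameterize
anything richer), then truncated to physical ranges: strains ≥ −100%, RURE
clipped to [0, 1], time metrics ≥ 0. Consequently a clipped feature's
sample mean converges to the *clipped* Gaussian mean, which is what the
convergence test asserts (closed form, 3 SE at n = 10⁴).

Survival is exponential per phenotype — baseline 0.004/month, phenotype 1
multiplied by $e^{\log 2.69}$ — with censoring uniform over a 160-month
window. Those three constants were derived jointly from the emulated
study's shape: ~13-year maximum follow-up, roughly 30% events overall, and
a planted phenotype-1 hazard ratio of 2.69. The generator is
bit-reproducible given its seed.

What passing tests on this cohort do **not** show: robustness to correlated
features, non-Gaussian tails, informative censoring, or measurement error
that depends on image quality — none of which the generator produces.

## 5. Clustering and the majority rule

Features are z-scored (population SD) so every metric weighs equally; rows
with missing features are dropped, not imputed. Clustering is Ward's
minimum-variance criterion on Euclidean distances (`ward.D2` form — heights
are Euclidean, merges monotone). maxTTP is computed and carried alongside
but excluded from the default 25-feature clustering vector: it is highly
collinear with sdTTP and would implicitly double-weight timing; a flag
restores it.

The number of clusters is a majority vote over 12 validity indices, each
voting by its own optimality rule: maximize (Calinski-Harabasz, silhouette,
Dunn, Krzanowski-Lai, point-biserial, Ratkowsky-Lance), minimize
(Davies-Bouldin, C-index, McClain-Rao), elbow (Ball-Hall by largest
successive drop; Hartigan by the classic "smallest k with H ≤ 10" rule,
falling back to the largest drop), and the gap statistic with Tibshirani's
first-SE rule on uniform reference draws (B = 25, fixed seed, so selection
is deterministic given data and seed). Vote ties go to the smallest k —
the conservative choice. The suite is pluggable; majority-rule behavior,
not any particular index census, is the contract, and the recovery tests
(median ARI and modal-k rate over 20 simulated cohorts) exercise exactly
that.

## 6. Survival analysis

Kaplan-Meier, pairwise log-rank, and Cox fitting are delegated to the
`survival` package, with the package fixing the conventions: time in months
from the index examination, Breslow tie handling, 95% CIs as
$\exp(\hat\beta \pm 1.96\,SE)$, and **per-SD standardization of continuous
covariates by default**. The scaling default matters: hazard ratios for
volume indices on a per-mL/m² scale are visually indistinguishable from 1
and incomparable across covariates with different units; per-SD HRs put the
binary phenotype flag and the continuous covariates on one readable scale.
Binary 0/1 covariates are never rescaled. `scaling = "unit"` restores raw
per-unit coefficients. Patients with a prior valve replacement are included
by default (they remain at risk of re-operation); `exclude_prior_pvr`
reproduces the corresponding sensitivity design. The tests cross-check
every piece against independent oracles: hand product-limit values,
a brute-force hypergeometric log-rank accumulation, the closed-form
two-group exponential rate-ratio MLE, exact-ties agreement on tie-free
data, and planted-HR CI coverage over 100 simulated cohorts.

## 7. Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) pixel indices; physical x/y axes are
  image right/up; angles counterclockwise from the anterior reference.
* Bilinear interpolation clamps to the image bounds; leaving the bounds
  flags the trajectory.
* Deformation-gradient normal equations are rejected at reciprocal
  condition number < 1e-10 (collinear neighborhoods).
* Cox convergence uses the `survival` defaults tightened to eps = 1e-10,
  100 iterations; separation warnings are captured and reported as flags
  rather than silenced.
* All tie-breaks (TTP frame, SRCC lag, vote ties) resolve to the earliest /
  smallest / most conservative option and are asserted in tests.

## 8. Problem sizes used by the test suite

The suite validates strain recovery on the default phantom (4832 mask
pixels, 40 frames; segmental peaks within 3 pp of truth, observed ~0.04
pp), delay recovery at 1–4 frame delays, cluster recovery on 20 cohorts of
n = 198, and HR coverage on 100 cohorts — sizes chosen to match the
emulated study's scale while keeping a full run around half a minute.
`scripts/acceptance.R` recomputes the same quantities end-to-end from a
command-line seed.

## 9. Known limitations

Single-slice 2-D mechanics only: no long-axis (longitudinal) strain, no
3-D phantom, no torsion. Circumferential strain maps are computed but no
circumferential uniformity statistic is derived. The segment map is purely
angular about a static centroid, so it assumes a roughly centered,
convex cavity. The phantom's incompressibility is 2-D (area), which is a
modeling convenience, not a physiological claim — real myocardium conserves
volume three-dimensionally. Velocity estimation itself (the upstream
inverse problem) is explicitly out of scope.
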