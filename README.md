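# lvmech

Regional left-ventricular (LV) mechanics from short-axis myocardial velocity
fields: AHA 16-segment strain and strain-rate curves, per-slice mechanical
dyssynchrony statistics, unsupervised discovery of contraction-pattern
phenotypes, and survival analysis of those phenotypes.

## Who this is for

Quantifying *regional* LV function matters in populations where global
metrics (ejection fraction, global strain) hide localized disease — the
canonical example being repaired tetralogy of Fallot (rTOF), where chronic
right-ventricular volume overload produces paradoxical septal motion,
selectively depressed septal strain, and mechanical dyssynchrony, often with
a normal LVEF. `lvmech` implements the full analysis chain downstream of
velocity estimation: given per-pixel myocardial velocities for an apical,
mid, and basal short-axis slice (from any source — speckle/feature tracking,
phase-contrast MRI, or a learned velocity estimator), it produces segmental
strain curves, dyssynchrony indices, cluster phenotypes, and time-to-event
models. Because public velocity datasets for this population do not exist,
the package ships two fully tested simulators that stand in for real data:

* **a contracting-annulus phantom** — a 2-D incompressible annular LV whose
  regional strain and activation timing are known in closed form, used to
  validate every step of the strain engine; and
* **a cohort simulator** — four planted contraction phenotypes with
  realistic feature templates and phenotype-dependent time-to-event
  outcomes, used to validate the clustering and survival machinery.

## The quantities computed

For each slice, material points seeded on the end-diastolic (ED) myocardial
mask are tracked through the cycle by integrating the velocity field. The
local deformation gradient **F** is estimated per pixel by least squares
over its ED neighborhood, and with **C** = **F**ᵀ**F** the radial
engineering strain is

&nbsp;&nbsp;&nbsp;&nbsp;ε_r = √(e_rᵀ **C** e_r) − 1,

with e_r the ED unit radial direction (circumferential strain analogously).
Segmental curves are averages over the AHA segments (6 basal, 6 mid, 4
apical; apex cap 17 excluded). From the radial curves, four per-slice
dyssynchrony statistics are derived:

| statistic | definition | synchronous limit |
|---|---|---|
| sdTTP | population SD of segmental times to peak strain | 0 ms |
| maxTTP | largest segmental time to peak | T/2 for the phantom |
| SRCC | mean absolute pairwise lag maximizing the circular cross-correlation of segmental strain-rate curves | 0 ms |
| RURE | Σ_t A0(t) / Σ_t (A0(t)+A1(t)), with A0/A1 the order-0/1 Fourier magnitudes of strain around the circumference | 1 (→ 0 for opposing-wall motion) |

Patient-level feature vectors (16 segmental peak radial strains + 3 × sdTTP,
SRCC, RURE) are z-scored and clustered with Ward's minimum-variance method
on Euclidean distances; the number of clusters is chosen by majority vote of
12 cluster-validity indices (Calinski-Harabasz, silhouette, Davies-Bouldin,
Dunn, C-index, gap statistic, Hartigan, Krzanowski-Lai, Ball-Hall,
point-biserial, McClain-Rao, Ratkowsky-Lance). Progression-free survival is
analyzed per phenotype with Kaplan-Meier estimates, pairwise log-rank tests,
and a multivariable Cox proportional-hazards model with Breslow tie
handling.

## Worked example

A mid-ventricular phantom in which one sector (anterolateral) activates
100 ms late:

```r
library(lvmech)
spec <- phantom_spec(activation_delay_ms = c(0, 0, 0, 0, 0, 100))
ph <- generate_phantom(spec)
an <- analyze_cine(ph$cine)
an$summary
#>  slice       segment peak_RS_pct TTP_ms
#>    mid      anterior    19.85552    525
#>    mid  anteroseptal    19.88316    500
#>    mid  inferoseptal    19.88748    500
#>    mid      inferior    19.88748    500
#>    mid inferolateral    19.84474    525
#>    mid anterolateral    16.63003    600
#> global RS: 19.1 % (peak_of_mean)
an$dyssynchrony
#>  slice sdTTP_ms maxTTP_ms  SRCC_ms    RURE
#>    mid 35.35534       600 33.33333 0.93041
```

The analytic mid-wall peak strain for this phantom is 19.85%: the five
on-time segments recover it to within 0.04 percentage points, and the
delayed segment peaks exactly 100 ms late (600 vs 500 ms). The dyssynchrony
statistics match their construction truths — sdTTP = 100·√5/6 ≈ 37.3 ms
within one frame, SRCC = 100/3 ms to machine precision — and RURE drops
below 1 because the contraction is no longer circumferentially uniform.

Phenotype discovery and survival on a simulated 198-patient cohort:

```r
gen <- generate_cohort(cohort_spec(seed = 7))
std <- standardize_features(gen$cohort[, lv_feature_names()])
select_k(std$z, 2:8, seed = 7)$chosen_k
#> [1] 4
cox_fit(gen$survival, c("cluster1_flag", "LVEDVi", "gRS", "LVEF",
                        "LVSVi", "LVESVi"))
#> Cox PH fit (Breslow ties, sd scaling), loglik = -248.152, 4 iter
#>      covariate        hr    ci_low  ci_high      p_value
#>  cluster1_flag 4.2558694 2.2454241 8.066371 9.014904e-06
#>         LVESVi 1.3065551 0.9959006 1.714113 5.356409e-02
#>           LVEF 1.1279483 0.8478898 1.500510 4.083270e-01
#>         LVEDVi 1.0463031 0.7663726 1.428483 7.756910e-01
#>          LVSVi 0.9752935 0.7382241 1.288494 8.602418e-01
#>            gRS 0.9384471 0.7025492 1.253553 6.671286e-01
```

The majority vote recovers the four planted phenotypes, and the Cox model
identifies the dyssynchronous septal-dysfunction phenotype (`cluster1_flag`,
planted hazard ratio 2.69) as the dominant risk factor; the per-seed
estimate (here 4.26, 95% CI 2.25–8.07) fluctuates around the planted value
with ~95% CI coverage across simulations.

The same chain is available as a pipeline with CSV/PNG artifacts and run
manifests:

```r
run_pipeline("all", default_config(seed = 1), "lvmech_out")
```

or from a shell via `Rscript inst/cli/lvmech.R all --seed 1 --out lvmech_out`.

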