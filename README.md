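# oftmech

Biomechanics of the embryonic heart outflow tract from 4D optical coherence
tomography (OCT).

At Hamburger–Hamilton stage 18 (~3 days), the chick heart outflow tract
(OFT) is a valveless, three-layered tube — myocardium, cardiac jelly
shaped into two spiraling endocardial cushions, endocardium — that closes
peristaltically after every beat to prevent backflow. The mechanical
stimuli its cells experience (circumferential strain and Laplace wall
stress in the myocardium, wall shear stress on the endocardial cushions)
guide septation and valve formation. `oftmech` is an R implementation of
the full measurement chain used to quantify those stimuli from 4D OCT:

* **synthetic data** — a parametric digital phantom of the beating OFT
  (tapered tube, spiral cushions, peristaltic closure for ~half the cycle,
  speckle, depth attenuation, wrapped Doppler phase, physiological
  pressures) with complete ground truth;
* **reconstruction** — cardiac-period estimation, phase-lag recovery
  between unsynchronized planes, folding into a 196-phase canonical cycle,
  M-mode/M-phase extraction;
* **segmentation** — gradient-vector-flow snakes with label-specific,
  isophote-gated forces for the outer/inner myocardium and endocardium,
  with temporal propagation, plus centerline and cross-section selection;
* **kinematics** — perimeter, area, effective radius, circumferential
  strain `ε(t) = (C_max − C(t))/C_max`, area shortening fraction
  `ASF = (A_max − A_min)/A_max`, radial velocity, shape factor,
  expansion/contraction/closure timing;
* **doppler** — `V_z = λ₀·Δϕ/(4π·n·τ)` (±12 mm/s at the ±π wrap limit for
  λ₀ = 1310 nm, n = 1.3, τ = 21 µs), temporal unwrapping (doubling the
  range), angle correction `V = V_z/cosθ`, wrap-plateau flagging;
* **wall stress** — pressure folding and phase alignment, linear axial
  interpolation between ventricular and aortic-sac sites, Laplace law
  `σ = P·R/h`;
* **hemodynamics** — a quasi-steady, mass-conserving flow model of the
  moving tapered elliptical lumen (`Q(z,t) = Q₀(t) − ∫₀ᶻ ∂A/∂t dz′`,
  elliptical-duct resistance `R_hyd = 4µ(a²+b²)/(πa³b³)`), centerline
  velocities and wall-shear-stress maps
  `τ = 2µU₀·√(cos²s/a² + sin²s/b²)`.

Everything user-facing takes and returns tibbles, pipes cleanly, and has
`autoplot()`/`tidy()`/`glance()` methods. See the vignette
(`vignettes/oft-biomechanics.Rmd`) for the models, assumptions, parameter
choices and limitations.

## Worked example

```r
library(oftmech)

cfg <- phantom_config()            # 5 planes, T = 0.37 s, 140 fps, seed 1
report <- run_pipeline(cfg)        # simulate -> ... -> flow (~3 min)

tidy(report)[, c("plane", "R_max_mm", "R_min_mm", "dR_mm",
                 "peak_eps_myo", "T_closure")]
#> # A tibble: 5 × 6
#>   plane R_max_mm R_min_mm  dR_mm peak_eps_myo T_closure
#>   <int>    <dbl>    <dbl>  <dbl>        <dbl>     <dbl>
#> 1     1    0.210    0.140 0.0704        0.335     0.561
#> 2     2    0.200    0.130 0.0700        0.350     0.561
#> 3     3    0.190    0.120 0.0706        0.371     0.556
#> 4     4    0.170    0.110 0.0604        0.355     0.561
#> 5     5    0.150    0.120 0.0306        0.204     0.556
```

The segmented radii recover the phantom's 0.21→0.15 mm taper and
0.14→0.12 mm systolic minima to better than 1%; peak circumferential strain
declines distally (0.34 proximal vs 0.20 at the outlet — the distal OFT
barely contracts), and each lumen is closed for ~0.56 of the cycle. Peak
Laplace wall stress rises distally instead (radius falls slower than
thickness):

```r
attr(report$stress, "peaks")
#> # A tibble: 5 × 2
#>   plane peak_sigma_pa
#>   <int>         <dbl>
#> 1     1          691.
#> 2     2          713.
#> 3     3          754.
#> 4     4          791.
#> 5     5          926.
```

`report$flow_summary` locates the peak wall shear stress on the cushion
surfaces (minor-axis ends, ellipse parameter s = π/2) of the distal
tract; `plot_wss_map(report$wss_map)` shows the spiral high-shear ridge
following the cushions along the tube, and `autoplot(report$kinematics)`,
`autoplot(report$stress)`, `autoplot(report$flow)` plot the per-plane
series.

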