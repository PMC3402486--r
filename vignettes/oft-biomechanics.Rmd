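---
title: "Quantifying outflow-tract biomechanics from 4D OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying outflow-tract biomechanics from 4D OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oftmech)
```

## The problem

At Hamburger–Hamilton stage 18 (~3 days of incubation) the chick heart is a
valveless tube. Its outflow tract (OFT) — the segment connecting the
primitive ventricle to the aortic sac — acts as a primitive valve: a
peristaltic-like wave of wall contraction presses two cardiac-jelly cushions
together and closes the lumen from the proximal to the distal end after each
ejection. The biomechanical stimuli experienced by the wall layers
(circumferential strain and wall stress in the myocardium, wall shear stress
on the endocardium) steer growth and remodeling, and their quantification
requires combining 4D optical coherence tomography (OCT) imaging, Doppler
velocimetry, pressure measurements, and a hemodynamic model.

`oftmech` implements that analysis chain as testable code. Because no public
imaging data exist for this preparation, the package ships a parametric
digital phantom that emulates the imaging and physiology of the preparation
with full ground truth, so every stage — synchronization, segmentation,
kinematics, Doppler conversion, wall stress, flow and wall shear stress —
can be verified end to end.

## The phantom and what it emulates

`phantom_config()` describes a tapered tube, 600 µm long, sampled by five
fixed cross-sectional planes. Per plane, the inner myocardial radius
oscillates between a diastolic maximum (0.21 → 0.15 mm proximal → distal)
and a systolic minimum (0.14 → 0.12 mm); the bright myocardial ring has
thickness h(z) decreasing 60 → 30 µm distally. Between myocardium and
lumen sits a dark cardiac-jelly layer shaped into two opposing cushion
lobes whose orientation rotates along the tube (default 0.15°/µm, i.e. 90°
over the tract). The lumen is the inner circle minus the cushions: an
ellipse whose major semi-axis hugs the myocardium (separated by a thin
`d_min` = 10 µm jelly film, the tethered region between cushions) and whose
minor semi-axis collapses to zero when the cushions appose.

Key temporal choices:

* **Activation.** The myocardial radius follows a raised cosine peaking at
  phase 0.68 of the cycle (T = 0.37 s, ~2.7 Hz). The lumen opening factor is
  the same cosine clipped below the cushion-contact level, so each plane's
  lumen is closed for exactly `closure_fraction` (default 0.52) of the
  cycle — "about half", with the contiguous closed interval the analysis
  stages must cope with.
* **Peristalsis.** The activation at depth z lags the inlet by
  z / wave-speed (default 40 mm/s, i.e. ~4% of the cycle across the tract),
  so closure travels proximal → distal and the whole-tract closed fraction
  stays within 10% of the per-plane value.
* **Closed-lumen rendering.** The apposed endocardial layers are rendered
  as a mid-level slit of 18 µm full thickness. The endocardium is
  *not* given a distinct intensity: as in real OCT of this preparation, it
  is indistinguishable from blood, and the analysis treats the lumen–wall
  interface as the endocardium.
* **Flow.** The inlet volume flow is a squared-sine pulse (peak
  1.7 mm³/s, chosen to put peak centerline velocities at 30–35 mm/s —
  enough to exceed the ±12 mm/s Doppler wrap limit at a 58.4° beam angle,
  as the study's mid-tract plane does). Flow at depth z follows from exact
  mass conservation with the moving wall, so the peristaltic squeeze-out is
  reproduced. The Doppler phase channel is rendered by inverting the
  phase–velocity relation (below) and wrapping into (−π, π], plus Gaussian
  phase noise (sd 0.15 rad).
* **Image statistics.** Multiplicative gamma speckle (contrast 0.3) and
  exponential depth attenuation (1 mm⁻¹) along the beam axis. These are
  free parameters of the phantom — plausible OCT statistics, not claims
  about any instrument.
* **Pressures.** Raised-cosine-cubed pulses at the cardiac frequency,
  sampled at 100 Hz, peaking at exactly 196 Pa (ventricle) and 180 Pa
  (aortic sac).

What the phantom does **not** emulate: longitudinal wall motion (planes are
fixed in space and the tube does not slide through them; an optional flag
modulates jelly area in antiphase with the ~20% longitudinal stretch, off by
default), A-scan-level interferometry, red blood cells, and the S-shaped 3D
curvature of the real heart (the phantom tube is straight, so the
curvature-induced velocity skew cannot appear). Passing tests therefore
demonstrate correctness of the algorithms under realistic speckle, closure,
wrapping and desynchronization — not performance on real embryo data.

## Reconstruction: one canonical cycle from unsynchronized planes

Each plane is acquired independently over ≥4 cycles, starting at a random
cycle phase. `estimate_period()` collapses a sequence to a scalar activity
signal — the mean absolute frame-to-frame intensity difference, chosen
because it is invariant to static intensity offsets (a normalized-correlation
variant is available) — and finds the first dominant autocorrelation peak,
refined by parabolic interpolation (typically within 1% of truth; period
drift in the study itself was bounded at 7%). `estimate_phase_lag()`
circularly cross-correlates two planes' activity signals over one period;
on the phantom the recovered lags are within a fraction of a frame of truth.
`synchronize()` shifts each plane by its lag, folds the cycles (per-pixel
median across cycles at equal phase; the Doppler channel uses the circular
mean, since a median of wrapped angles is ill-defined), and resamples to 196
uniform phases. The global phase origin is anchored at the most-constricted
state of plane 1, found as the minimum of its mean-intensity lumen proxy.
Because closure is a plateau, that anchor is arbitrary within it — which is
why the flow stage later locates its window from the measured opening
rather than assuming fixed phases.

## Segmentation: snakes with label-specific forces

Boundaries are delineated by a closed snake: 64 vertices, implicit update
with circulant pentadiagonal internal energy (elasticity α = 0.1, stiffness
β = 0.05), external force sampled from a gradient-vector-flow-style
diffusion (40 iterations, µ = 0.2) of an edge map.

Two implementation choices matter and were set by experiment on the phantom:

* **Isophote-gated edge maps.** A plain gradient-magnitude edge map lets
  the strong jelly–myocardium edge capture the endocardial snake wherever
  the jelly is thin, and thresholded class maps bias boundaries toward the
  brighter side when the two adjacent tissue levels are asymmetric. Each
  label therefore uses gradient magnitude gated by a Gaussian band around
  the midpoint intensity of the *two classes that actually meet at that
  boundary* (classes estimated once per sequence by k-means, k = 4). This
  leaves the zero crossing of the force at the geometric boundary.
* **Smoothing scale.** σ = 1.5 px: at σ = 2 px the 18 µm closed-lumen slit
  (≈3.6 px) is blurred below detectability and the collapsed endocardium is
  lost.

Initialization is by radial rays through the appropriate class mask
(longest run of the bright band for the myocardium; first run from the
lumen centroid for the endocardium, so the mid-level transition ring at the
jelly–myocardium interface is not picked up). Temporal propagation warm
starts the myocardial snakes from the previous frame warped by a coarse
optical-flow estimate (global translation from a least-squares gradient
fit, plus an isotropic scale from the bright-mask area). The endocardium is
re-initialized from the class map every frame: its topology collapses at
closure, and a warm start from the collapsed slit cannot re-open. A >50%
area jump triggers from-scratch re-segmentation, which is also how a
corrupted frame is recovered from.

Accuracy on the phantom: inner/outer myocardial areas within ~1% of truth
(noiseless) and ≤5% per frame over the full cycle at default noise;
endocardial area within ~5% while the lumen is open wide, Dice ≥ 0.9.
Relative area error of the collapsed slit is large (the slit is 2–4 px
wide); slit-phase endocardial metrics (minimum perimeter and area) are
reported but should be read as resolution-limited, which also matches the
study's own caution about the closed-lumen endocardium. Depth attenuation
is removed before all of this by a mirror-symmetry estimate of the
exponential decay rate along the beam.

## Kinematics

From each plane's contour series the package computes perimeter C and
enclosed areas by the shoelace formula, and derives: effective myocardial
radius R = sqrt(A/π); circumferential strain in the contraction-positive
convention ε(t) = (C_max − C(t))/C_max with the cycle maximum as reference
(for the myocardium, C = 2πR); area shortening fraction
ASF = (A_max − A_min)/A_max; radial velocity dR/dt by centered differences
on the periodic phase grid (no smoothing by default); the fitted-ellipse
shape factor λ; and the expansion/contraction/closure time fractions, where
"closed" means area within 5% of the dynamic range above the cyclic minimum
(`eps_closed` — the threshold is a convention, there being no independent
definition of "closed" in image terms). Two conversions of closed-lumen
perimeter/area to an endocardial layer thickness are provided (collapsed
slit, t = 2A/C, and thin annulus, t = A/C); neither is privileged, and with
Table-type inputs they bracket the plausible monolayer thickness.

## Wall stress

Pressure and wall motion cannot be recorded in the same subject, so their
phase relation must be imposed: by default the folded, phase-resampled
ventricular trace is shifted so its peak coincides with peak lumen area at
plane 1 (a config override exists; the distal-greater-than-proximal stress
ordering is insensitive to this choice, and the same shift is applied to
the aortic-sac trace so the measured inter-site delay is preserved).
Pressure along the tract is the linear blend
P(s,t) = (1−s)·P_vent + s·P_as of the two sites, and the circumferential
myocardial stress is the thin-wall Laplace estimate σ = PR/h with R the
effective inner radius and h the cycle-resolved wall thickness derived from
the contours (difference of outer and inner effective radii). With the
default taper — radius falling faster than pressure, thickness falling
faster still — peak stress increases distally as an emergent property; it
is never hard-coded, and the tests assert it only under that taper.

## Doppler velocimetry

The inter-A-scan phase shift converts to axial velocity as
V_z = λ₀·Δϕ/(4π·n·τ) with λ₀ = 1310 nm, n = 1.3, τ = 21 µs — ±12 mm/s at
the ±π wrap limit — and to flow speed as V = V_z/cosθ, which multiplies
noise by exactly 1/cosθ (hence the noisy 84° inlet plane). Unwrapping is
1-D in time along the extracted centerline series, each contiguous
open-lumen segment separately; closed-lumen frames are reported as missing,
never zero, so peak statistics ignore closure. Unwrapping doubles the
usable range (24 mm/s axial, ≈46 mm/s at 58.4°); samples at or beyond the
doubled limit are flagged as potential wrap plateaus and excluded from
model comparisons.

## Hemodynamics: a reduced-order moving elliptical duct

The study's transient 3D finite-element model is out of scope here; the
package implements the quasi-steady reduction that the low Reynolds number
(Re ≈ 5) justifies and that the study itself evaluated against its
transient solution. The lumen is an elliptical duct with semi-axes a(z,t) ≥
b(z,t) fitted per plane per phase and interpolated along z by a
shape-preserving monotone cubic (no overshoot into negative axes). At each
step of the simulated window (default 0.43 T–0.93 T in 200 steps, Δt =
0.925 ms at T = 370 ms; the pipeline instead derives the window from the
measured opening so it tracks the canonical phase origin):

* mass conservation with the moving wall gives
  Q(z,t) = Q₀(t) − ∫₀ᶻ ∂A/∂t dz′;
* the inlet flow solves the scalar equation
  ΔP(t) = ∫₀ᴸ R_hyd·Q dz with the elliptical-duct resistance density
  R_hyd = 4µ(a²+b²)/(πa³b³), µ = 3×10⁻³ Pa·s;
* centerline velocity is U₀ = 2Q/(πab) and wall shear stress at boundary
  parameter s is τ = 2µU₀·sqrt(cos²s/a² + sin²s/b²), maximal at the minor
  axis ends — the cushion surfaces — and spiraling along the tract with
  them.

Axial integrals use composite Simpson on 101 points; ∂A/∂t uses centered
differences. Numerical safeguards: a 1 µm floor regularizes degenerate
fitted axes, and any step in which some section's minor semi-axis is at or
below `closed_mm` = 12 µm (the scale of the apposed endocardial layers) is
treated as closed with zero through-flow — without this, the squeeze flow
through a nearly-closed section produces unphysical velocity spikes. An
optional first-order inertial correction (ρ = 1060 kg/m³, a literature
density, not a measured one) is off by default. The solver reproduces the
circular and elliptical Poiseuille closed forms to <0.1%, conserves mass to
<10⁻⁶ (discretely, to machine precision) and is grid-converged to <1% at
the default resolution. Because the quasi-steady reduction is least
trustworthy while the lumen is barely open — the opening and closing
transients, roughly the first and last tenth of the window — the summary
peak statistics (`flow_summary()`) exclude that fraction at each end;
squeeze flow through near-contact sections there would otherwise dominate
the reported peaks.

One caveat the tests make explicit: the phantom's prescribed inlet pulse
and its pressure pulses are independent parameters, so the model-vs-Doppler
comparison on the phantom agrees in timing and shape but not amplitude
(relative RMS ≈ 0.4 in the default report). The subject-specific agreement
reported for real data has no phantom analogue; the round-trip tests
(solution → rendered phase → extracted velocity, <5%) are what validate the
Doppler chain quantitatively.

## Problem sizes and reproducibility

Defaults: 5 planes of 120×120 px at 5 µm pitch, 4 cycles at 140 fps
(~208 frames/plane), 196 canonical phases, 200 flow steps on 101 axial
points. A full `run_pipeline()` at these sizes takes ~3 minutes on one CPU;
tests use the same geometry with fewer planes or phases where a property
does not depend on them. All randomness flows from the single seed in
`phantom_config()`; a fixed seed gives bit-identical phantoms, reports and
artifacts (each report carries the seed and a config hash).

## Known limitations

* The phantom's tube is straight: curvature-driven flow skew and
  out-of-plane centerline motion are not represented, and the centerline
  module sees a nearly trivial geometry (a curved-centerline variant is
  exercised synthetically in the tests).
* Slit-phase endocardial metrics are resolution-limited (above).
* The Laplace stress is a thin-wall estimate with all load carried by the
  myocardium; no Lamé/finite-elasticity analysis, no jelly load sharing.
* The flow model is 1-D in z: no secondary flows, no entrance effects, no
  fluid–structure interaction; longitudinal wall velocity is neglected in
  the solve.
* Residual (growth) strains are invisible to fixed-plane cyclic analysis
  and are not modeled.
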