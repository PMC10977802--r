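---
title: "Modelling HIFU ablation of uterine adenomyosis: methods and design choices"
author: "hifusim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIFU ablation of uterine adenomyosis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifusim)
```

## The problem

High-intensity focused ultrasound (HIFU) ablates focal uterine adenomyosis
noninvasively by concentrating acoustic energy at a focal point inside the
lesion, heating tissue until it coagulates. Adenomyotic tissue differs from
uterine fibroid tissue in a way that matters thermally: it appears brighter
on T2-weighted MRI, consistent with higher blood perfusion, and perfusion
carries heat away. A protocol tuned for fibroids (here the "Group A" preset)
therefore under-doses adenomyosis, and a denser, hotter, longer protocol
("Group B") compensates. `hifusim` provides the simulation chain needed to
make that argument quantitative — acoustic field, bioheat dynamics, thermal
dose, multi-point protocol replay — plus the clinical outcome indices used
to evaluate such treatments and a synthetic cohort generator so the whole
pipeline is testable without patient data.

## Acoustic model

The source is a focused spherical-cap (bowl) transducer discretized into
quasi-uniform sub-elements (`discretize_bowl()`). Ring areas use the exact
spherical-zone formula, so the summed element area equals the analytic cap
area $2\pi R(R-\sqrt{R^2-a^2})$ to machine precision. The true clinical
array geometry is unpublished; the package default, $F = 130$ mm,
$a = 64$ mm, $f_0 = 1$ MHz, is a representative abdominal-HIFU bowl and
every result is reported against a declared, configurable geometry.

Pressure is computed two ways, which check each other:

* **Rayleigh–Sommerfeld summation** (`rs_pressure()`):
  $p(\mathbf{x}) = \frac{i\rho c k}{2\pi}\sum_e u_e A_e
  \frac{e^{-i\hat k r_e}}{r_e}$, with complex $\hat k = k - i\alpha$
  carrying attenuation. Against an independently implemented O'Neil on-axis
  closed form the summation agrees to better than 1% over
  $[0.5F,\,1.5F]$ when the bowl is tiled at a quarter wavelength.
* **Angular-spectrum propagation** (`asa_propagate()`): plane-to-plane FFT
  marching with propagator $e^{-ik_z\Delta z}$,
  $k_z = \sqrt{\hat k^2 - k_x^2 - k_y^2}$. Evanescent components are
  hard-truncated and the grid zero-padded by a factor 2 against
  wraparound (an optional angular-restriction filter is off by default).

The hybrid driver `simulate_field()` evaluates the Rayleigh integral once
onto a pre-focal plane and marches the field through the volume, using the
local layer's sound speed and attenuation per step. The default layered
path — water standoff, 10 mm fat, 15 mm muscle, then myometrium containing
the focus, with $c$ = 1482/1450/1580/1540 m/s, $\rho$ = 994/950/1050/1050
kg/m³, $\alpha$ = 0.002/0.48/0.74/0.50 dB/cm at 1 MHz (power-law exponent
1.1, absorption fraction 0.9) — is a literature-typical stand-in declared as
configuration. Interface transmission losses are neglected (soft-tissue
impedance contrasts are small); nonlinear propagation, cavitation and
aberration are out of scope.

Protocol intensities are interpreted as spatial-peak, pulse-average focal
intensity *in situ*, and `calibrate_focal_intensity()` scales the element
drives so the computed focal peak matches the target exactly (linearity
makes the scaling $\sqrt{I_{target}/I_{peak}}$ exact). Because of this
in-situ calibration, the treatment simulations compute their beam template
in a homogeneous myometrium-like medium: the layered path changes the
uncalibrated amplitude, which calibration removes, and only mildly perturbs
the focal beam shape.

## Thermal model and dose

`pennes_solve()` integrates the Pennes bioheat equation
$$\rho c_p \frac{\partial T}{\partial t} =
  \nabla\!\cdot\!(k\nabla T) + Q - w_b c_b (T - T_a)$$
with explicit forward-time centred-space stepping, Dirichlet faces at
$T_a$, and a stability guard
$\Delta t \le \rho c_p/(6k/h^2 + w_b c_b)$ that refuses unstable steps with
a suggested value. The explicit scheme was chosen for transparency: it is
verified against a perfusion-only exponential decay (relative error
$<10^{-3}$) and the 3-D heat kernel's variance law ($<1\%$ peak error), and
it satisfies a discrete maximum principle under the stability bound.
Heating is $Q = 2\alpha_{abs} I$ (`heat_source_from_intensity()`).

Thermal defaults: $k = 0.56$ W/(m·K), $\rho = 1050$ kg/m³,
$c_p = 3600$ J/(kg·K), $c_b = 3617$ J/(kg·K), $T_a = 37$ °C; perfusion
$w_b = 0.7$ kg/(m³·s) for muscle/fibroid-like and $2.5$ kg/(m³·s) for
myometrium/adenomyosis-like tissue. Only the *identification*
(fibroid → muscle, adenomyosis → myometrium) and its direction are part of
the modelling premise; the numeric rates are declared defaults exposed in
`perfusion_defaults()` and overridable everywhere.

Thermal dose uses the standard Sapareto–Dean convention
(`cem43_accumulate()`): $CEM43 = \sum R^{43-T}\Delta t$ with $R = 0.5$
above 43 °C and 0.25 below, ablation at 240 equivalent minutes
(inclusive threshold, `ablated_volume()`). One numerical guard: the dose
exponent is clamped at $T - 43 = 100$ °C. The linear bioheat model has no
boiling or property saturation, so a long sonication can push the focal
voxel to unphysical temperatures; the clamp keeps the accumulated dose
finite without moving the 240-min ablation contour, which lives at far
lower temperatures.

## Protocol replay

`sonication_preset("A")` and `"B"` return the two studied parameter sets
(4 mm / 0.8 kW/cm² / 60% / 6 s vs 2 mm / 1.0 kW/cm² / 70% / 7 s, both at
1 MHz, 10 Hz PRF, 3 s transitions). `plan_grid()` lays a cubic lattice at
the point interval inside the lesion ellipsoid, excluding the deepest
10 mm (the protocol rule of staying a centimetre above the deepest lesion
margin is read conservatively as an exclusion slab; the offset is an
argument since the clinical sentence admits a coverage-floor reading too).
Points are ordered shallow-to-deep, boustrophedon within planes; treatment
order is configurable in principle because near-field preheating makes dose
order-dependent, and the declared default keeps later (deeper) points from
sonicating through already-heated tissue.

`simulate_treatment()` replays the protocol point by point — heat for the
per-point time, cool for the transition time — accumulating dose
continuously. Two modelling choices keep it desk-scale:

* **Template translation.** One focal field template is computed and
  translated to each treatment point (homogeneous focal neighbourhood
  assumption) instead of re-solving the diffraction problem per point.
* **Duty-cycle averaging.** The 100 ms pulse period is far below tissue
  thermal time constants, so the default heating is time-averaged
  ($Q \times$ duty/100). Explicit 10 Hz on/off pulsing is available
  (`pulsing = "explicit"`), and the two agree on peak CEM43 within 5% at
  matched time step — the residual difference is the convexity of the dose
  rate over the pulse ripple.

Timing accounting is exact arithmetic: $n$ points take
$n\,t_{point} + (n-1)\,t_{trans}$ seconds with
$n\,t_{point}\,d/100$ seconds of emission; both total per-point time and
duty-scaled on-time are reported because clinical "sonication time" could
denote either.

`compare_params()` and `perfusion_sweep()` wrap deterministic single-point
(or 3×3 mini-grid) treatments to expose the optimization rationale: on the
adenomyosis-perfusion phantom the B preset ablates strictly more per point
than A, and ablated volume is monotone non-increasing in perfusion, with
high enough perfusion suppressing lesion formation entirely. No formal
optimization is performed — the package evaluates and compares, which is
all the underlying argument needs.

## Grid and problem sizes

The package defaults are chosen so a full simulate–compare–sweep cycle runs
in minutes on one core: treatment templates and phantoms use 0.5 mm voxels
(the acoustic driver itself accepts any spacing; 0.25 mm — roughly
$\lambda/6$ in water at 1 MHz — reproduces textbook focal profiles and is
used where beam detail matters), templates span ±10 mm laterally and
±15 mm axially around the focus, and comparison phantoms are
~2 cm lesions in ~3 cm domains. At these sizes the focal spot is resolved
by 3–4 voxels across its −6 dB width, sufficient for the volume integrals
reported; halving the voxel changes single-point ablated volumes by less
than the voxel discretization granularity itself.

## Outcome indices

`ellipsoid_volume()` ($0.523\,L\,W\,H$, the MRI three-axis estimate),
`avsr()` ($100(1 - V_{after}/V_{before})$, negative for growth),
`npvr()` (nonperfused volume over a reference volume) and
`dii_effective()` (dysmenorrhea improvement index $\le 3$) implement the
efficacy indices, and `summarize_cohort()` produces per-group, per-timepoint
medians with type-7 quartiles and effective-DII proportions with their
counts, complete-case per cell and with empty cells flagged missing rather
than zero. Two NPVR denominators exist in practice — the defining baseline
volume and the same-timepoint volume — and both are supported explicitly;
presentation rounding is one-decimal half-away-from-zero
(`round_half_out()`), applied only at display.

## Synthetic cohort

`generate_cohort()` draws a cohort with the structure the outcome layer
expects: group sizes 20/46, lognormal baseline volumes (median 68.6 cm³,
log-sd 1.0 — matching a roughly 37–149 cm³ interquartile spread), per-group
truncated-normal AVSR at 1 m/3 m (means 21.5/27.6 for A, 21.0/51.0 for B,
sd 20), immediate NPVR (means 34.1 vs 77.1, sd 20, truncated to [0, 100]),
ordinal DII from a Bernoulli effective/ineffective draw on the logit scale
with per-timepoint baselines and a group-B log-odds shift of log(3.69),
and monotone dropout (12% at 1 y, 36% marginal at 3 y). A logistic refit of
effective DII on group over 200 generated cohorts recovers the configured
odds ratio. The generator is a structural emulator, not a patient model: it
reproduces the descriptive moments it is configured with, generates AVSR
and DII improvement independently within a participant (their real-world
correlation is unknown), has no within-participant longitudinal
autocorrelation in symptom scores, and no informative dropout. Tests
passing on this cohort demonstrate that the pipeline computes its indices
and recovers known generator parameters — not that the generator resembles
any particular clinical population beyond those configured moments.

`generate_phantom()` builds the matching deterministic tissue phantoms:
myometrium-like background with an ellipsoidal lesion whose perfusion is
set by the scenario label (fibroid-as-muscle vs adenomyosis-as-myometrium).

## Numerical conventions and degenerate inputs

* Time convention $e^{+i\omega t}$, outgoing waves $e^{-ikr}$; axial axis
  $z$ increases away from the transducer (deeper = larger $z$).
* Quartiles are type-7 (linear interpolation); a convention had to be fixed
  for determinism.
* Targets coinciding with source elements, backward angular-spectrum steps,
  unstable time steps, empty plans (lesion thinner than the deep margin),
  empty cohorts, zero calibration fields, and out-of-range ordinal scores
  all raise immediate, specific errors rather than propagating NA or Inf.
* All simulation components are seed-free deterministic; only
  `generate_cohort()` consumes randomness, through one seeded generator
  whose state is restored on exit.

## Known limitations

Linear acoustics only (no harmonics or cavitation-enhanced heating, both of
which raise real focal heating); constant tissue properties (no perfusion
shutdown on coagulation, which in reality accelerates late-sonication
lesion growth); plane-layered beam path without refraction at curved
interfaces; fixed-temperature domain faces standing in for skin cooling and
deep perfusion baths; template translation assumes a homogeneous focal
neighbourhood. These simplifications bias ablated volumes conservatively
and are shared by most treatment-planning-grade simulators; the package's
claims are therefore directional (preset orderings, monotonicities) rather
than absolute lesion-size predictions.
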