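# hifusim

Simulation and outcome analysis of high-intensity focused ultrasound (HIFU)
ablation of focal uterine adenomyosis.

HIFU ablates a lesion by raster-scanning a focused beam over a lattice of
treatment points, heating each for a few seconds. Adenomyotic tissue is
better perfused than uterine fibroid tissue (it is brighter on T2-weighted
MRI), and perfusion carries heat away — so a protocol tuned for fibroids
under-doses adenomyosis. `hifusim` implements the simulation chain that
quantifies this and the clinical indices used to evaluate such treatments:

* **Acoustics** — Rayleigh–Sommerfeld summation over a discretized focused
  bowl, $p = \frac{i\rho c k}{2\pi}\sum_e u_e A_e\, e^{-i\hat k r_e}/r_e$,
  hybridized with FFT angular-spectrum propagation through layered
  attenuating tissue; calibration of the element drives to a target
  spatial-peak focal intensity.
* **Bioheat + dose** — explicit finite-difference Pennes equation
  $\rho c_p \partial_t T = \nabla\cdot(k\nabla T) + Q - w_b c_b (T - T_a)$
  driven by absorption heating $Q = 2\alpha_{abs} I$, with Sapareto–Dean
  CEM43 thermal dose (ablation at 240 equivalent minutes).
* **Protocol replay** — the conventional fibroid preset (Group A: 4 mm,
  0.8 kW/cm², 60 %, 6 s) and the simulation-optimized adenomyosis preset
  (Group B: 2 mm, 1.0 kW/cm², 70 %, 7 s); lattice planning with a deep-margin
  exclusion, multi-point treatment simulation, parameter comparison across
  perfusion scenarios.
* **Outcome metrics** — ellipsoid lesion volume ($0.523\,L\,W\,H$),
  nonperfused volume ratio (NPVR), volume shrinkage ratio (AVSR),
  clinically effective dysmenorrhea improvement index (DII ≤ 3), and cohort
  summary tables.
* **Synthetic data** — a seeded cohort generator (two unequal groups,
  lognormal baseline volumes, group/time-dependent shrinkage, ordinal DII
  with a configurable group odds ratio, follow-up dropout) and deterministic
  tissue phantoms, so the entire pipeline is testable without patient data.

## Worked example

```r
library(hifusim)

## the imaging worked example: a 5.7 x 5.1 x 4.0 cm lesion
round_half_out(ellipsoid_volume(5.7, 5.1, 4.0))   # 60.8 cm3
round_half_out(avsr(60.8, 12.0))                  # 80.3 % shrinkage

## compare the two protocol presets on an adenomyosis-perfusion phantom
ph   <- generate_phantom(domain = c(22, 22, 26), voxel = 0.5,
                         lesion_semiaxes = c(5, 5, 7),
                         scenario = "adenomyosis-myometrium")
tmpl <- focal_intensity_template(spacing = 0.5, lateral_halfwidth = 7,
                                 axial_halfwidth = 9)
compare_params(list(sonication_preset("A"), sonication_preset("B")),
               ph, template = tmpl)
#>   label               scenario peak_T_C peak_cem43_min ablated_cm3 cm3_per_min
#> 1     A adenomyosis-myometrium 67.68962   2.785951e+05    0.013125   0.1312500
#> 2     B adenomyosis-myometrium 84.94771   3.584474e+10    0.046500   0.3985714
```

One sonication with the conventional preset reaches a focal peak of ~68 °C
and ablates 0.013 cm³ of the well-perfused phantom; the optimized preset
reaches ~85 °C and ablates 3.5× more per point — the directional effect the
optimized parameters were designed for. A ten-point Group B treatment takes
`treatment_timing(10, sonication_preset("B"))` = 97 s of protocol time with
49 s of emission.

```r
## synthetic cohort -> descriptive tables
coh <- generate_cohort(cohort_config(seed = 1))
summarize_cohort(coh)
#> Clinically effective DII (percent (n/N)):
#>  group timepoint         cell
#>      A        1m   80 (16/20)
#>      B        1m 93.5 (43/46)
#>  ...
```

A thin command-line wrapper over the same functions lives in
`inst/cli/hifusim.R` (subcommands `simulate-field`, `simulate-treatment`,
`compare-params`, `synth-cohort`, `metrics`).

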