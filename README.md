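# oxyshear

Shear-induced red blood cell (RBC) elongation under oxygenated and
deoxygenated conditions: a desk-scale analysis chain from ektacytometry
deformability curves to the spatial distribution of the elongation index
(EI) in a vessel.

`oxyshear` is aimed at hemorheology and hemodynamics researchers who
work with LORRCA-style deformability data and want to propagate it into
blood-flow simulations: it covers the calibration mathematics, the
non-Newtonian constitutive law, validated laminar flow solvers for
straight geometries, and the mapping from computed shear stress to
cell elongation.

## What it computes

* **Elongation index** — EI = (a − b)/(a + b) from the axes of the
  laser-diffraction ellipse; dimensionless, larger = more deformed.
* **Lineweaver–Burke parameters** — the EI–SS curve is treated as the
  hyperbola EI(SS) = EImax·SS/(SS½ + SS); ordinary least squares on
  1/EI vs 1/SS yields EImax (asymptotic maximal elongation), SS½ (Pa,
  stress at half-maximal elongation) and the normalised ratio SS½/EImax.
* **Two-term exponential calibration** —
  EI(SS) = c₁·e^(r₁·SS) − c₂·e^(−r₂·SS), fitted by bounded multi-start
  nonlinear least squares; built-in presets carry the published
  coefficient sets for oxygenated (`eq1_oxygenated`) and deoxygenated
  (`eq2_deoxygenated`) whole blood.
* **Casson rheology** — apparent viscosity
  μ(γ̇) = τ_y/γ̇ + 2√(τ_y μ_c)/√γ̇ + μ_c for γ̇ > 0 (0.0035 Pa·s
  otherwise), with hematocrit-dependent μ_c = μ₀(1 − Hct)^(−1/2) and two
  yield-stress presets.
* **Flow** — steady and pulsatile fully developed laminar flow of the
  Casson fluid in rigid channels/tubes (sinusoidal pulse 0.1–0.5 m/s,
  period 0.5 s, outlet gauge pressure 13.332 kPa by default), with a
  semi-analytic Casson–Poiseuille oracle, wall-shear-stress extraction
  and VTK export.
* **EI maps** — EI(τ) applied cell-wise to the shear-stress field;
  wall/centre elongation ratios per pulse phase; oxygenated versus
  deoxygenated comparison.
* **Synthetic data** — a seeded generator of LORRCA-like datasets
  (10 subjects × 2 replicates × 2 conditions × 2 phases on the canonical
  0.3–50 Pa ladder) plus fragmenting ghost-cell curves.

## Worked example

```r
library(oxyshear)

# 1. synthetic LORRCA dataset and Lineweaver-Burke parameterisation
curves <- generate_dataset(synth_config(seed = 42))
lb_fit_curves(curves) |>
  dplyr::group_by(condition, phase) |>
  dplyr::summarise(ei_max = mean(ei_max), ss_half_pa = mean(ss_half_pa),
                   .groups = "drop")
#>   condition    phase      ei_max ss_half_pa
#> 1 deoxygenated after_5Pa   0.626       1.03
#> 2 deoxygenated before_5Pa  0.637       1.15
#> 3 oxygenated   after_5Pa   0.638       1.37
#> 4 oxygenated   before_5Pa  0.652       1.54
```

Deoxygenation lowers SS½ (cells reach half-maximal elongation at lower
stress, i.e. deform more easily) and shear conditioning lowers it
further — the qualitative signature the generator builds in.

```r
# 2. fit a calibration to the oxygenated subject-mean curve
mean_oxy <- summarize_protocol(curves) |>
  dplyr::filter(condition == "oxygenated", phase == "before_5Pa") |>
  dplyr::rename(ei = mean_ei)
fit_ei_calibration(mean_oxy, condition = "oxygenated", seed = 42)
#> <ei_calibration> fitted_oxygenated (oxygenated)
#>   EI(SS) = 0.5496*exp(0.003611*SS) - 0.5202*exp(-0.5428*SS)
#>   fit domain [0.3, 50] Pa; R^2 = 0.9999487; monotone: TRUE
```

The recovered coefficients sit next to the generating preset
(0.5464, 0.00356, 0.5224, 0.5395) — the residual difference is the
sampling noise of 10 subjects.

```r
# 3. solve a steady channel flow and map the elongation field
field <- solve_steady(flow_problem(channel_geometry(), inlet = 0.3))
ei <- map_ei(field, cal_preset("eq1_oxygenated"))
ei
#> <ei_field> oxygenated (eq1_oxygenated), t = 0 s
#>   EI range [0.0240, 0.2533]; 4883 nodes below / 0 above fit domain
wall_center_ratio(ei)
#>   time_s ratio mean_wall_ei mean_center_ei
#> 1      0  6.17        0.245         0.0398
```

EI floors at the zero-stress value 0.0240 on the centreline and rises
to 0.253 at the wall (wall shear stress ≈ 1.06 Pa at 0.3 m/s): cells
near the wall are ~6× more elongated than in the lumen core. With
`solve_pulsatile()` the same summary is produced per pulse phase, and
`compare_conditions()` shows the deoxygenated map above the oxygenated
one in every cell. `run_pipeline()` chains all stages into a single
reproducible JSON report, and `inst/cli/rbc-oxyshear.R` exposes the
stages as shell subcommands.

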