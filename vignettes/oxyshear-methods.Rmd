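---
title: "From ektacytometry to vessel-scale elongation maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ektacytometry to vessel-scale elongation maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyshear)
```

## The problem

Red blood cells (RBCs) deform under shear, and how much they deform
depends on their oxygenation state: deoxygenated cells elongate more at
every shear stress than oxygenated ones. An ektacytometer (LORRCA)
quantifies this with the elongation index EI = (a − b)/(a + b) of the
laser-diffraction ellipse of a sheared suspension, measured across a
ladder of ten shear-stress levels from 0.3 to 50 Pa. `oxyshear`
implements the full desk-scale chain from such deformability curves to a
spatial map of EI inside a vessel:

1. **ektacytometry** — EI from diffraction axes; Lineweaver–Burke
   parameterisation (EImax, SS1/2, SS1/2/EImax) of EI–SS curves.
2. **calibration** — a two-term exponential EI(SS) model fitted by
   nonlinear least squares, giving an analytical, invertible bridge from
   shear stress to elongation.
3. **rheology** — the Casson yield-stress, shear-thinning model of whole
   blood viscosity with hematocrit-dependent parameters.
4. **flow** — steady and pulsatile laminar flow of the Casson fluid in
   straight channels and tubes, with a semi-analytic oracle.
5. **ei_map** — cell-wise application of the calibration to the computed
   shear-stress field, wall/centre summaries, and the oxygenated versus
   deoxygenated comparison.
6. **synth** — a seeded generator of LORRCA-like datasets providing
   ground truth for every statistical procedure in the chain.

## Deformability parameterisation

The Lineweaver–Burke approach treats the EI–SS curve as the hyperbola
EI(SS) = EImax·SS/(SS1/2 + SS) and fits the straight line 1/EI =
1/EImax + (SS1/2/EImax)·(1/SS) by ordinary least squares. The intercept
gives EImax (asymptotic maximal elongation) and slope/intercept gives
SS1/2 (stress at half-maximal elongation); lower SS1/2 means more easily
deformed cells. The linearisation is exact on a noiseless hyperbola, and
the test suite verifies recovery to 1e-10 relative error across random
parameter draws.

Points with EI ≤ 0 — seen for resealed ghosts that fragment above
5.15 Pa — are excluded with a warning before the fit: 1/EI is undefined
or negative there and the hyperbolic model only describes intact-cell
curves. The fit is unweighted by default (weighting is a deliberate
non-feature of the transformed-variable regression here), requires at
least three usable points, and treats a non-positive intercept as a
non-physical fit rather than returning a negative EImax.

Group summaries average replicates within subject first and then take
mean ± SE across subjects (n − 1 denominator), matching the usual
presentation of deformability data for 10 subjects measured in
duplicate. With a single subject the SE is reported as 0 by convention.

## The two-term exponential calibration

The simulation needs EI at arbitrary stresses, so the discrete curve is
replaced by

EI(SS) = c₁·exp(r₁·SS) − c₂·exp(−r₂·SS),

with c₁, c₂ dimensionless and r₁, r₂ in 1/Pa. Built-in presets carry the
published coefficient sets for oxygenated (0.5464, 0.00356, 0.5224,
0.5395) and deoxygenated (0.5483, 0.003966, 0.5006, 0.598) whole blood,
both on the fit domain 0.3–50 Pa. Within the admissible coefficient
region (c₁, c₂ > 0, r₁ ≥ 0, r₂ > 0) the derivative
c₁r₁e^{r₁SS} + c₂r₂e^{−r₂SS} is positive everywhere, so every
calibration in this family is strictly increasing and invertible; the
monotonicity flag on fitted objects is therefore a defensive check that
can only trip for hand-constructed coefficient sets outside the fitting
bounds.

Fitting uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with c₁, c₂ ∈ (0, 1], r₁ ∈ [0, 0.1] 1/Pa and
r₂ ∈ (0, 5] 1/Pa. The bounds encode the physical EI range and the order
of magnitude of the published coefficients. Two-exponential models have
local minima, so the optimiser is restarted from a data-driven initial
guess (plateau amplitude from the largest EI, zero-stress offset from
the lowest-stress point) plus seven points of a seeded Latin hypercube
over the bounds; the converged start with the smallest residual wins.
The restarts are deterministic given the seed, and on noiseless
model-generated data every seed reaches the zero-residual global
minimum. R² is defined on untransformed EI residuals,
1 − SSres/SStot, matching a single goodness-of-fit number for the
nonlinear fit; it is computed on the subject-mean curve of one condition
(the pipeline default uses the before-conditioning phase, since the
published coefficients are not attributed to a phase and the fitting
path is agnostic).

Inversion is bracketed root-finding (`stats::uniroot`) on [0, 100] Pa;
the upper bracket extends to twice the measured ladder because mapped
fields can reach the EI plateau. Round trips hold to 1e-10.

## Casson rheology

Apparent viscosity is piecewise: for shear rate γ̇ > 0,

μ(γ̇) = τ_y/γ̇ + 2·√(τ_y·μ_c)/√γ̇ + μ_c,

with yield stress τ_y = μ∞² and infinite-shear (Casson) viscosity
μ_c = N∞²; at γ̇ ≤ 0 the nominal whole-blood viscosity 0.0035 Pa·s is
used. The Casson viscosity is parameterised by hematocrit as
N∞ = √μ₀·(1 − Hct)^(−1/4), so μ_c = μ₀(1 − Hct)^(−1/2); with plasma
viscosity μ₀ = 1.45e-3 Pa·s and Hct = 0.4 this gives
μ_c ≈ 1.872e-3 Pa·s, within 1% of the minimum simulated blood viscosity
reported for the carotid simulation (1.886e-3 Pa·s). The exponent
placement in the source typography is ambiguous; this reading is the
dimensionally consistent one that reproduces that field minimum, which
is why the package adopts it.

Two yield-stress presets are kept rather than guessing one away:

* `literal`: μ∞ = 0.625·Hct (in √Pa), i.e. τ_y = (0.625·Hct)² —
  0.0625 Pa at Hct 0.4. This is the printed form.
* `calibrated`: μ∞ = √(0.1·(0.625·Hct)³), the classical
  hematocrit-cubed yield correlation — τ_y ≈ 1.56e-3 Pa at Hct 0.4.
  With it, the reported maximum simulated viscosity 2.072e-2 Pa·s is
  attained near γ̇ ≈ 0.15 1/s, a plausible minimum shear rate in a
  near-stagnation sinus region, so this preset is recommended when
  reproducing field extrema.

A configurable viscosity cap (default 2.072e-2 Pa·s, the reported field
maximum) bounds the stiffness of the law near stagnation; it can be
disabled (`mu_cap = Inf`), in which case the material genuinely yields
and sub-yield regions form solid plugs. Shear rate from a velocity
gradient tensor is γ̇ = √(2 D:D) with D the symmetric part, invariant
under rotations.

## Flow solvers

The in-scope geometries are straight rigid channels and tubes. For
those, incompressible laminar flow is *exactly* unidirectional — the
advective term vanishes identically and continuity is satisfied by
construction — so the package solves the cross-stream momentum equation

ρ ∂u/∂t = G(t) + ∂/∂y( μ(|∂u/∂y|) ∂u/∂y )

(cylindrical form in tubes) rather than a full 2-D projection scheme.
This is a deliberate design choice: for fully developed flow the 1-D
formulation is the exact reduction of the Navier–Stokes equations, every
field contract (no-slip, divergence-free, momentum residual, mass
conservation) is retained and tested, and the desk-scale cost drops by
orders of magnitude. Gravity is dropped: with a single outlet gauge
pressure (13.332 kPa) fixing the datum of a horizontal vessel, ρg only
shifts the hydrostatic reference. Blood density defaults to
1060 kg/m³.

Discretisation: conservative second-order finite volumes on cross-stream
nodes (walls on nodes, so no-slip is exact); face viscosities evaluated
from face gradients and lagged one Picard iteration with 0.7
under-relaxation in steady solves; backward-Euler time stepping with two
Picard sub-iterations per step in pulsatile solves. The pressure
gradient G(t) is the Lagrange multiplier that enforces the prescribed
inlet mean velocity, computed exactly per step by linear superposition
of two tridiagonal solves (Thomas algorithm). Bulk velocity uses
composite Simpson quadrature, which is exact for the parabolic profile,
so the solver reproduces the Newtonian limit to rounding. The advective
CFL number at peak velocity is checked (≤ 0.5) before time stepping even
though the reduced equation has no advection: it keeps the streamwise
resolution and time step mutually consistent.

The sinusoidal pulse is v(t) = (v_min+v_max)/2 +
(v_max−v_min)/2·sin(2πt/T) with defaults 0.1/0.5 m/s and T = 0.5 s;
phase zero at the ascending mean is an arbitrary deterministic choice
since only the extremes and period are constrained. Pulsatile runs start
from the steady solution at v(0), integrate at least `n_periods`
periods, and extend until two successive periods agree to 1e-3·v_max in
the profile (with the default problem this takes a handful of periods
because the flow-rate constraint pins the bulk mode). Twenty phases of
the final period are stored.

The independent oracle is the semi-analytic Casson–Poiseuille tube
solution: τ(r) = τ_w·r/R exactly, γ̇(r) by closed-form inversion of the
(optionally capped) Casson law, u(r) by inward integration from the
wall. Tests verify the numerical tube solution against it (L2 < 1% at
128 radial cells, error ratio ≥ 3 when halving the spacing), the
Newtonian closed forms (centreline/mean = 1.5, WSS = 3μv/h), the
yield/no-flow criterion, the plug region, and quasi-steady pulsatile
behaviour at low Womersley number. Wall shear stress uses one-sided
second-order differences at the wall, exact for parabolic profiles.

Default problem sizes — channel of half-height 3.15 mm (the main
carotid lumen scale) and length 60 mm, 64 cross-stream × 256 streamwise
intervals, dt = 2e-4 s — were chosen so a full pulsatile solve completes
in seconds; unit tests use coarser grids where the property under test
permits.

## EI mapping

The calibration argument is the *local* shear-stress magnitude
τ = μγ̇, not wall shear stress: the elongation map colours the whole
lumen, and WSS only enters wall-band summaries. Below 0.3 Pa the fitted
function is extrapolated rather than clamped — the reported minimum
mapped EI (0.033) lies below the lowest measured EI (0.084), which is
direct evidence the original analysis extrapolated too; the count of
nodes outside the fit domain is recorded on the result. At zero stress
the map floors at EI(0) = c₁ − c₂ (0.0240 oxygenated, 0.0477
deoxygenated; pointwise difference 0.0237).

Wall and centre bands default to 10% of the half-height/radius — not a
measured quantity, so it is a configuration knob with a stated default —
and the wall/centre ratio is reported per stored phase because the
underlying claim (elongation 5–10× higher at the wall than at the lumen
centre) holds for sections of the pulse, not its entirety: at
low-velocity phases the ratio drops well below 5, at peak phases it
sits in or above the band. Because both preset calibrations are
strictly increasing and pointwise ordered, the deoxygenated map exceeds
the oxygenated map in every cell of any solved field, and EI ranks
inversely to viscosity wherever the stress exceeds the yield stress
(the "negative image" property, tested as a Spearman correlation below
−0.9).

## The synthetic generator

No public ektacytometry dataset accompanies the study design, so the
generator emulates its structure: 10 subjects × 2 replicates × 2
conditions × 2 phases on the canonical ladder. Mean curves are the
preset calibrations; conditioning (5 Pa for 300 s) adds +0.01 EI at the
levels ≤ 1.65 Pa, the range where the improvement is reported as
significant; subjects share a Gaussian offset (SD 0.01) and measurements
add i.i.d. Gaussian noise (SD 0.005). The noise scale was chosen once so
that group SEs at n = 10 land in the few-×10⁻³ range typical of
published deformability curves; the between-subject SD is a placeholder
in the same range, since true between-subject variance is not published.
Ghost-cell curves rise to ≈0.3 by 2.91 Pa and fall below zero above
5.15 Pa, exercising the exclusion and poor-fit paths.

What passing tests therefore show: the estimators recover known truth
under Gaussian noise of realistic scale with the study's design, and the
pipeline is deterministic given a seed. What they cannot show: behaviour
under real LORRCA artifacts (heteroscedastic noise, drift,
subject-by-stress interactions), which the generator does not emulate.

## Numerical choices and degenerate inputs

* Steady Picard convergence: relative profile change < 1e-11 and face
  viscosity change < 1e-9, max 400 iterations; the reported momentum
  residual is recomputed with the viscosity consistent with the final
  profile and must be < 1e-6 relative.
* Zero inlet velocity short-circuits to the exact quiescent solution at
  outlet pressure.
* Zero shear-rate faces take the 0.0035 Pa·s fallback branch; with the
  default cap this only occurs at exact symmetry points and does not
  perturb the solution.
* Calibration inversion tolerates 1e-12 slack at the range edges and
  returns 0 exactly at the zero-stress elongation.
* Ties in the multi-start fit are broken by the first minimal-residual
  start in seed order, making results reproducible.
* All curve tables are validated (positive stresses, EI strictly inside
  (−1, 1)); mixed shear-stress grids are a hard error in summaries.

## Known limitations

* The straight-geometry solvers do not reproduce bifurcation features —
  stagnation points, sinus recirculation, secondary flow — and the
  package makes no claim on the 3-D field extrema; those enter only as
  plausibility bounds on the calibration and rheology.
* The Casson parameter readings are presets precisely because the source
  typography is ambiguous; both are kept and documented rather than
  resolved.
* The two-term exponential family is intrinsically monotone, so
  fragmenting (ghost) curves can only be flagged by a poor R², not by a
  non-monotone fit.
* Walls are rigid and the pulse is a pure sinusoid; physiological
  waveforms and compliance are out of scope.
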