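---
title: "Simulating magnetic induction hyperthermia on a voxel mouse phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating magnetic induction hyperthermia on a voxel mouse phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihsim)
```

## The physical problem

Magnetic induction hyperthermia treats a tumor by loading it with a
colloidal suspension of single-domain magnetic nanoparticles ("magnetic
fluid") and exposing it to an alternating magnetic field. The particles'
magnetization lags the field (Néel and Brownian relaxation), dissipating
field energy as heat; the therapeutic goal is to hold the tumor at or above
42 °C — where tumor cells are driven into apoptosis — while sparing
surrounding tissue (kept below roughly 46 °C and ideally much cooler).

`mihsim` simulates this treatment end to end for a scalp melanoma on a
mouse head, at desk scale:

1. **Coil field.** A Helmholtz pair (two identical coaxial multi-turn
   coils) produces a highly uniform alternating field at its midpoint. The
   field is computed by Biot–Savart superposition over the individual
   winding loops, on the axis from the closed-form loop formula and off
   axis from the complete-elliptic-integral solution.
2. **Nanoparticle power.** The local field strength drives the Rosensweig
   relaxation-loss model: equilibrium susceptibility from the Langevin
   curve, loss power
   $P_0 = \pi \mu_0 \chi_0 H_0^2 f \cdot \frac{2\pi f\tau_{\mathrm{eff}}}
   {1+(2\pi f\tau_{\mathrm{eff}})^2}$,
   scaled by an empirical correction factor $\alpha = 0.55$ into the
   volumetric heat source applied over the tumor.
3. **Bioheat transfer.** The Pennes equation
   $\rho c\,\partial T/\partial t = \nabla\!\cdot\!(k\nabla T) +
   \rho_b C_b \omega_b (T_b - T) + Q_m + \alpha P_0$
   is integrated on a voxelized layered head phantom for 300 s from a
   uniform 37 °C start.
4. **Exposure screening.** Quasi-static induced-field estimates
   $E = \pi f B r$ and $J = \sigma E$ provide order-of-magnitude safety
   bounds per tissue.

The reference scenario is fixed by published hardware and exposure
parameters: 180 turns per coil wound over radii 0.14–0.15 m and an axial
width of 0.05 m, driven at 8 A and 100 kHz; a tumor of face area
451.52 mm² and thickness 2 mm loaded at volume fraction
$\varphi = 0.003$; 300 s of heating.

## The phantom: what it emulates and what it does not

The synthetic-data stage (`build_head_phantom()`) replaces the CT-derived
anatomical mouse of the reference scenario with a parametric phantom: a brain
ellipsoid (semi-axes 8 × 6 × 6 mm), a 1 mm skull shell, a 1 mm scalp
shell, a muscle stub descending to a 37 °C far boundary, and the tumor as
a right circular disk (radius $\sqrt{451.52/\pi} \approx 11.99$ mm,
thickness 2 mm) whose center defines the coordinate origin at the coil
center. Shell thicknesses are not published; the defaults are typical
murine scale and every geometric parameter is configurable.

Two geometry decisions were genuinely open:

* **Tumor shape.** Only area and thickness are published; the disk applies
  the area constraint to the flat face. A conformal cap would hug the
  scalp, but its parametrization would invent curvature data the
  reference scenario does not give.
* **Head placement under the disk.** A disk resting *tangentially* on the
  curved scalp touches it in a single point and leaves >95 % of the tumor
  base over air — anatomically wrong for a cutaneous melanoma, which
  arises within the skin. The default therefore seats the tumor base half
  a scalp thickness into the scalp (`tumor_embed`), so the tumor locally
  replaces the outer half of the skin and a scalp layer remains directly
  beneath it. This is an anatomical judgement, not a fit: the voxelized
  contact between a flat disk and a curved small head remains far smaller
  than the conformal, head-wide contact of the anatomical model.

That last point bounds what the phantom can reproduce. Temperatures of
tissues heated *through* the contact (scalp beneath the tumor, brain
maximum) land close to the published anatomical results, but quantities
that integrate over the whole interface — notably the fraction of brain
volume warmed above 38.5 °C (published ≈10 %) — cannot be matched: in
this phantom the brain couples to the tumor only near the apex, and the
computed fraction stays below 1 %. Conversely the tumor-center probe sits
1 mm *above* the contact patch, so it is cooled a couple of degrees below
the insulated perfused-block value, where the anatomical model reports an
essentially lumped 43.9 °C. Both deviations are reported as computed; the
package does not adjust geometry to meet either number, and passing the
remaining checks should be read as validating the physics stages, not as
anatomical fidelity.

Voxelization is by voxel-center membership on an isotropic grid (default
0.5 mm) with the origin on a voxel corner; the tumor's axial extent is
half-open so the disk spans exactly `thickness / voxel_size` layers. The
tumor volume then converges to 903.04 mm³ as the grid is refined.

## Tissue properties

The registry (`tissue_table()`) ships as a version-controlled CSV holding
the published dielectric and thermophysical values verbatim: conductivity
and relative permittivity; density, specific heat, thermal conductivity,
blood perfusion rate (1/s) and metabolic heat (W/m³) for scalp, muscle,
skull, brain, tumor, the nanofluid, and the tumor/nanofluid mixture. Two
published oddities are used as printed rather than "corrected": the
mixed-tissue conductivity 0.5316 W/(m·K) lies *below* pure tumor's 0.535
even though the added particles conduct at 40 W/(m·K) (no standard mixing
rule — volume-weighted or Maxwell–Garnett — reproduces it), and the scalp
conductivity 0.000451 S/m is far below typical skin values. Column
headers published as W·m⁻¹ / kg·m⁻¹ are treated as W/m³ and kg/m³ for
dimensional consistency with the bioheat equation.

Mixture density and heat capacity follow volume-fraction mixing,
$(1-\varphi)x_{\mathrm{tumor}} + \varphi\,x_{\mathrm{fluid}}$, which
reproduces the tabulated 1072.4 kg/m³ and 3651.1 J/(kg·K) at
$\varphi = 0.003$ at the printed rounding. Perfusion and metabolic heat of
the mixture are inherited from the host tumor (0.01392 s⁻¹, 5790 W/m³):
the particles are neither perfused nor metabolically active. Dielectric
values are not published for tumor/mixed tissue and default to muscle, the
closest tabulated soft-tissue surrogate; they only enter the
order-of-magnitude exposure stage.

## Coil model and calibration

Each coil's 180 turns are placed on a uniform 12 (radial) × 15 (axial)
grid spanning the published winding envelope; only the envelope, not the
layout, is published. The center-plane separation is likewise not
published. Its default is the classical Helmholtz condition (separation =
mean radius, 0.145 m), which gives a center flux density of 8.927 mT —
within 5 % of the published 8.5621 mT; `calibrate_separation()` solves for
the separation that reproduces a requested center field exactly (0.1552 m
for 8.5621 mT, still within the apparatus scale). The reference
configuration uses the calibrated separation. Reported magnitudes are peak
(amplitude) values of the sinusoidal drive, matching the published mT
figures; RMS reporting is available behind a flag. Tissue has relative
permeability 1, so the field with the phantom present equals the empty-coil
field and $H = B/\mu_0$ everywhere.

## Nanoparticle source: a calibrated, not predicted, power

The study reports the loss power $P_0 = 673{,}920$ W/m³ at
$H_0 = 6814.2$ A/m and 100 kHz but not the particle parameters
($M_d$, $V$, $\tau_{\mathrm{eff}}$) behind it. The default
`nanoparticle_spec()` therefore fixes magnetite-like values
($M_d = 446$ kA/m, 19 nm diameter, body temperature 310.15 K) and solves
$\tau_{\mathrm{eff}}$ so that the Rosensweig expression reproduces the
reported power at the reported field (`calibrate_relaxation_time()`).
The frequency response $x/(1+x^2)$, $x = 2\pi f\tau_{\mathrm{eff}}$, is
unimodal with two solutions for any sub-peak target; the faster (sub-peak,
$x<1$) branch is the default, consistent with the short Néel times of
small superparamagnetic particles ($\tau_{\mathrm{eff}} \approx 4.7\times
10^{-7}$ s here). $P_0$ is consequently a calibrated input — the thermal
stage is reproducible, but the power itself is not an independent
prediction. The source $\alpha P_0$ (with $\alpha = 0.55$, applied to
$P_0$ only, not to metabolic heat) is spread uniformly over the tumor,
evaluated at the center-point field strength as in the original procedure;
a per-voxel mode exists behind `source$per_voxel_field` and changes probe
temperatures by well under 0.05 °C, since the field ripple across the
tumor is below 1 %. The source is held constant over the 300 s (no
temperature feedback), and the equilibrium susceptibility is evaluated at
body temperature.

## Bioheat solver

The solver is a cell-centered finite-volume discretization on the tissue
voxels (air is excluded from the solve), with harmonic-mean face
conductivities $2k_1k_2/(k_1+k_2)$ across tissue interfaces — the choice
that keeps the normal flux continuous across material jumps. Three
published ambiguities are resolved on physical grounds:

* **Perfusion sign.** The equation as published carries
  $+\rho_b C_b\omega_b(T - T_b)$, a heat *source* growing with
  temperature, which diverges and cannot produce the published saturating
  heating curve. The standard Pennes sink form
  $\rho_b C_b\omega_b(T_b - T)$ is implemented.
* **Blood properties.** $\rho_b$ and $C_b$ are never published; the
  defaults 1060 kg/m³ and 3650 J/(kg·K) (a tumor-like blood surrogate)
  make the lumped perfused-block solution land on the published 43.9 °C
  plateau, and are configurable.
* **Boundary conditions.** None are published. The tissue–air surface is
  insulated by default — for the 2 mm tumor disk (volume-to-surface ratio
  ≈ 1 mm) any realistic film coefficient with a cool ambient would drain
  heat at the same order as the source term itself, contradicting the
  published saturating curve, so free convection is evidently not part of
  the original model. A convective (Robin) option
  (`bc_air = list(type = "convective", h, T_ambient)`) is available for
  sensitivity studies. The far face of the muscle stub is held at 37 °C.

Metabolic heat applies in every tissue from $t = 0$ even though the
initial field is uniform 37 °C; the resulting sourceless drift is bounded
by $Q_m/(\rho_b C_b \omega_b)$ per tissue and stays below 0.3 °C over
300 s for every published parameter set (the test suite checks this).

Time integration is backward Euler (implicit) with $\Delta t = 1$ s by
default; the operator is constant, so its sparse Cholesky factor is
computed once and reused across the 300 steps. A forward-Euler scheme is
available and guarded by the stability bound
$\Delta t \le \min \rho c\,\Delta x^2/(6k)$ (0.307 s at 0.5 mm, limited by
the mixed tissue); both schemes agree within 0.05 °C on the reference
scenario at matched steps. The implicit scheme conserves enthalpy exactly
for insulated, unperfused problems, satisfies the discrete maximum
principle, and reproduces the closed-form exponential relaxation
$T_b + \Delta T_{ss}(1-e^{-t/\tau})$ of a homogeneous perfused block
(`perfused_block_temperature()`) to solver precision — the independent
oracle for the thermal stage. For the tumor parameters
$\Delta T_{ss} = (\alpha P_0 + Q_m)/(\rho_b C_b \omega_b) \approx 6.99$ K
and $\tau \approx 72.7$ s, giving 43.88 °C at 300 s and a 42 °C crossing
near 91 s.

### Problem sizes and numerical checks

The reference run uses 0.5 mm voxels (≈58,000 tissue unknowns, ≈20 s on
one core). Grid convergence is verified on a geometrically reduced head
(small brain, small tumor, identical discretization and boundary logic) so
that the halved-voxel comparison stays desk-sized; the tumor-center
temperature at 300 s moves by less than 0.1 °C when the voxel is halved
from the 0.5 mm default. The explicit/implicit comparison runs the full
head at 1 mm. Degenerate inputs are rejected rather than coerced: voxels
coarser than 1 mm (the 2 mm tumor must be at least two voxels thick),
probes on air voxels, sources outside the tumor, unlabeled tissue,
explicit steps beyond the stability bound.

## Induced-field estimates

The exposure stage deliberately stops at the quasi-static bound
$E = \pi f B r$ on each tissue's widest circular path about the coil axis,
with $J = \sigma E$. The published anatomical extrema (63.1, 33.5, 35.828,
1.49, 10.496 V/m) come from a full eddy-current finite-element solution in
heterogeneous anatomy — including the skull's shielding of the brain —
which a desk-scale estimator cannot and does not attempt to reproduce; the
report header says so. The tumor-path estimate (≈32 V/m at the reference
field) sits within a factor of two of the published tumor range, which is
the only check asserted.

## What the reference run reproduces

Running `run_pipeline(mih_config())` recomputes, deterministically:
the calibrated center flux density (8.5621 mT), the center field strength
(6813.5 A/m vs the published 6814.2, from $B/\mu_0$), the calibrated loss
power chain ($P_0 \approx 673{,}900$ W/m³, source ≈ 370,600 W/m³), the
tumor maximum (43.7 °C vs published 44.2), tumor coverage ≥ 42 °C
(91.6 % vs published ≈ 93 %), the scalp beneath the tumor (40.3 °C vs
published 41), and the brain maximum (38.8 °C vs published 39.8). The
known, geometry-driven exceptions discussed above are the tumor-center
probe (41.1 °C vs published 43.9, cooled by the adjacent contact patch)
and the brain coverage fraction (<1 % vs published ≈ 10 %). All of these
numbers are produced by the test suite and by `scripts/acceptance.R`; none
are asserted from this text.

## Known limitations

* No temperature-dependent tissue properties, vascular trees, or thermal
  damage integrals (Arrhenius/CEM43); coverage fractions only.
* No eddy-current or SAR heating: all heating comes from the nanoparticle
  relaxation loss, as in the scenario being emulated.
* No coil impedance, skin effect, or supply modeling; the conductor
  conductivity is carried as metadata only.
* The parametric phantom bounds anatomical fidelity as described above;
  conclusions about absolute normal-tissue dose in a real mouse require
  the anatomical geometry.
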