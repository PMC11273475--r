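# mihsim — magnetic induction hyperthermia simulation on a voxel mouse phantom

`mihsim` is an R package for desk-scale treatment simulation of magnetic
nanoparticle hyperthermia of a murine scalp melanoma. It is written for
researchers in bioelectromagnetics and thermal medicine who want an open,
tested re-implementation of the standard simulation chain — coil field,
nanoparticle loss power, bioheat transfer, thermal dose — without a
commercial finite-element environment.

## The model

A Helmholtz coil pair (N = 180 turns per coil wound over radii
0.14–0.15 m, width 0.05 m, driven at I = 8 A, f = 100 kHz) produces the
field by Biot–Savart superposition of its winding loops; on the axis each
loop contributes

    B(x) = μ₀ I R² / (2 (R² + x²)^{3/2}),

and off the axis the complete-elliptic-integral loop solution is used.
The tumor is uniformly loaded with single-domain magnetic nanoparticles at
volume fraction φ = 0.003, whose relaxation (Rosensweig) loss power in the
alternating field is

    P₀ = π μ₀ χ₀ H₀² f · 2πfτ_eff / (1 + (2πfτ_eff)²),
    χ₀ = χᵢ (3/ξ) L(ξ),   χᵢ = μ₀ φ M_d² V / (3 k_B T),   L(ξ) = coth ξ − 1/ξ,

with ξ = μ₀ M_d H₀ V / (k_B T). The source α·P₀ (correction factor
α = 0.55) heats the tumor in the Pennes bioheat equation

    ρc ∂T/∂t = ∇·(k ∇T) + ρ_b C_b ω_b (T_b − T) + Q_m + αP₀,

solved implicitly on a voxelized layered head phantom (scalp/skull/brain
ellipsoids plus a 451.52 mm² × 2 mm tumor disk) for 300 s from 37 °C.
Quasi-static induced-field estimates E = π f B r, J = σE provide
per-tissue exposure bounds. All tissue parameters ship in a
version-controlled CSV registry.

## Worked example

```r
library(mihsim)

res <- run_pipeline(mih_config(), quiet = TRUE)  # ~20 s on one core
print(res)
#> Magnetic induction hyperthermia run
#>   B center      : 8.5621 mT  (H = 6813.5 A/m)
#>   loss power P0 : 673822 W/m^3  (source alpha*P0 = 370602 W/m^3)
#>   tumor center  : 41.14 degC at 300 s
#>   tumor region  : min 40.80 / mean 43.27 / max 43.73 degC; 91.6% >= 42 degC
#>   brain region  : max 38.76 degC; 0.5% >= 38.5 degC
```

Reading the report: the calibrated coil delivers 8.5621 mT (peak) at its
center, i.e. H = B/μ₀ = 6813.5 A/m at the tumor; the calibrated
relaxation-loss model converts that to ≈674 kW/m³ of particle heating, of
which α = 0.55 enters the tissue as ≈371 kW/m³. After 300 s the tumor
volume sits at 40.8–43.7 °C with 91.6 % of it at or above the 42 °C
therapeutic threshold, while the brain peaks at 38.8 °C — tumor-selective
heating with normal-tissue sparing. Probe heating curves are available via
`plot(res)` and `res$probes`; per-region statistics via `summary(res)`;
`dose_report(res)` returns the full JSON-serializable dose report, and
setting `mih_config(outdir = ...)` writes VTK snapshots, CSV probe curves
and the exposure table to disk.

Individual stages are exposed directly: `build_head_phantom()`,
`tissue_table()` / `mixture_properties()`, `coil_spec()` /
`helmholtz_axis_profile()` / `field_map_3d()` / `calibrate_separation()`,
`nanoparticle_spec()` / `relaxation_loss_power()`, `simulate_bioheat()`
with `perfused_block_temperature()` as its closed-form oracle, and
`exposure_report()`.

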