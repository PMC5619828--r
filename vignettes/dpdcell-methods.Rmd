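---
title: "dpdcell: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dpdcell: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`dpdcell` implements a three-component mesoscopic cell — triangulated
cell membrane, triangulated nucleus envelope, cross-linked filament
cytoskeleton (plus a chromatin network of identical construction inside
the nucleus) — inside a Dissipative Particle Dynamics (DPD) fluid. DPD
conserves mass and momentum, so the same particle framework supplies
both the cell mechanics and the hydrodynamics of the microfluidic
environment; it is scale-free, so the physical unit mapping is imposed
a posteriori (`unit_system()`).

## DPD layer

Every pair of particles within a cutoff interacts through a soft linear
repulsion of strength `a`, a dissipative force `−γ w² (r̂·v) r̂` and a
random force `σ w θ r̂ / √dt`, with `σ² = 2γk_BT` (fluctuation–
dissipation) and weight `w(r) = (1 − r/R_c)^s`, `s = 0.25`. The
generalised exponent softens the weight, which raises the Schmidt
number of the fluid at moderate `γ`. Parameters are a symmetric
type-pair table; filament rows carry two radii — a short repulsion
cutoff (0.5) with `a = 100` that prevents filament crossing, and a
thermostat cutoff (1.0) whose `γ` and range are deliberately free,
because they are the handles used to tune bulk cell viscosity.
Wall–wall pairs are excluded: wall particles are frozen.

Integration is the modified velocity-Verlet with `λ = 1/2`: forces at
the new positions are evaluated with half-step velocities, and the
random force carries the `1/√dt` scaling inside the integrator. The
pair noise `θ_ij` is drawn once per pair per step and shared by both
members (`θ_ij = θ_ji`), which is what makes the thermostat momentum
conserving. The noise is uniform with zero mean and unit variance —
the standard fast choice; only the first two moments enter the
discrete fluctuation–dissipation balance, which the test suite checks
directly (equilibrium temperature within 3% for `γ ∈ {30, 45, 65}`).

## Membranes

A membrane is a closed genus-0 triangulation whose vertices are DPD
particles. The in-plane elasticity is a wormlike chain (WLC) on every
edge plus a per-triangle `C₁/A` repulsion. `C₁` is set per triangle
from the balance of the regular network: for uniform edge length `l₀`,
`d/dl [3/2·U_WLC + C₁/A] = 0` at `l = l₀` gives
`C₁ = (3√3/16)·f_WLC(l₀)·l₀³`, with `f_WLC` the WLC tension. On a
perfectly regular mesh (icosahedron) the reference state is then an
exact equilibrium; on the near-uniform sphere meshes the residual
forces are small but nonzero — the reference state is still
stress-free in the aggregate because all reference quantities (edge
lengths, dihedral angles, area, volume) are measured on the
constructed mesh.

Bending is `k_b Σ (1 − cos(θ − θ₀))` over adjacent-triangle
dihedrals, with `θ₀` taken per dihedral from the constructed mesh (a
stress-free reference; a single global `θ₀` would frustrate any mesh
whose local curvature varies). Global area and volume constraints use
the quadratic penalties with coefficients `k_a`, `k_v`; the volume is
the signed sum over oriented triangles, and orientation is validated at
construction. Membrane viscosity follows the per-edge dissipative
force `−γ^T v_ij − γ^C (v_ij·r̂) r̂` with the matched random force
built from the traceless-symmetric part of a Gaussian Wiener-increment
matrix; with the enforced relation `γ^T = 3γ^C` the trace term
vanishes identically, and an isolated membrane equilibrates at `k_BT`
(tested).

**Sphere meshing.** Vertex counts are arbitrary (the calibrated cell
uses exactly 3500), so icosphere subdivision is not usable. Points are
seeded on a Fibonacci lattice, relaxed by soft point-repulsion on the
sphere, polished by Laplacian smoothing rounds interleaved with convex
hull re-triangulation (the hull of sphere-constrained points *is* the
triangulation), and triangulated by an in-package incremental 3D hull.
At 3500 vertices and 16 µm diameter the mean edge length is ≈ 0.513 µm
(printed reference 0.518, within 2%) and the enclosed volume is within
0.2% of the sphere.

**Nucleus.** The nucleus envelope uses the same construction with its
own `l_max` (1.2 µm vs 3.0 µm for the cell), bending constant and area
coefficient. Its diameter follows from the nuclear–cytoplasmic ratio
interpreted as a projected-area ratio: `D_n = D·√NC`. The vertex count
keeps the mean edge at ≈ 0.5 µm, matching the cell-surface resolution
(≈ 1085 vertices at `NC = 0.29`, `D = 16`).

## Cytoskeleton

Filaments are bead chains with spacing `r₀ = 0.5 µm` (nine particles
per 4 µm filament), harmonic springs `κ_fil (r − r₀)²` and straight
harmonic angles. The chosen spacing is the one value consistent with
the polymerization binding radius (0.5 µm) and with the arithmetic of
the printed densities: 3.5 filament particles/µm³ with 4 µm filaments
gives ≈ 389 filaments per 10³ µm³, and only then can 0.525 CLs/µm³
produce ≈ 2.1 cross-links per filament.

Cross-linking uses auxiliary CL particles. Two modelling choices here
are ours, because the source model does not constrain CL-particle
transport:

* **CLs couple to filaments through the thermostat only** (`a = 0`).
  Any soft repulsion of the tabulated magnitudes would put a multi-kBT
  barrier between a CL and the binding radius (0.25 µm), making the
  printed converged topology unreachable.
* **CL friction is low** (`γ = 4.5`). The friction of an auxiliary
  particle sets how fast formation converges — a transport property —
  not the converged topology, which is governed by the binding rules
  and network geometry. With the fluid-table friction the convergence
  time is an order of magnitude longer with the same endpoint.

Binding uses the distance from the CL particle to the **filament**
(point-to-segment over the chain polyline), with the nearest filament
particle as the bond partner; a CL binds at most two distinct
filaments, a filament particle carries at most one CL, and no CL joins
a filament to itself. Unbinding follows Bell's law, `κ(F) = κ⁰
exp(λF/k_BT)` for separations at or beyond the binding radius and `κ⁰`
below it (a slack tether carries no load); `κ⁰ = 78 s⁻¹`,
`λ = 3.5×10⁻⁵ µm` for CLs. Rates convert to per-step probabilities
`1 − exp(−κ Δt_phys)` through the time unit (33.3 µs per sim time
unit, from the viscosity-parameter mapping).

After the free-CL count converges (windowed relative change < 1% over
10⁴ steps), single-bound CLs are pruned and each doubly-bound CL is
merged into one direct filament–filament spring (`κ_CL`, stress-free
rest length), with `κ_CL/fil` anchor angles at `θ₀ = π/2` and a
`k_tor (1 − cos(φ − φ₀))` torsion over the quadruple (chain neighbour
of anchor A, anchor A, anchor B, chain neighbour of B), `φ₀` being the
constructed dihedral.

**Polymerization.** Before cross-linking, chains grow at their plus
end when another filament's particle lies within 0.5 µm (a local
monomer-availability proxy; an isolated filament does not grow) and
shrink at the minus end with a probability proportional to the surplus
of added over removed particles, the constant calibrated online so the
expected net change per iteration is zero — total filament length stays
within 5% over the phase.

**Cell integration.** The periodic-box network is carved to the cell
volume (chains split at exits; every retained particle strictly inside
the surface and outside the nucleus), chromatin is generated by the
same pipeline inside the nucleus, and filaments link spontaneously to
membrane vertices within 0.5 µm (cell) / 0.4 µm (nucleus), at most one
link per particle and per vertex, with Bell unbinding
(`κ⁰ = 30 s⁻¹, λ = 10⁻⁴ µm` cell; `κ⁰ = 78 s⁻¹, λ = 2×10⁻⁴ µm`
nucleus), run until the linked-vertex count converges.

## Walls, flow and the virtual experiments

Solid geometry is a union of signed-distance primitives (slabs,
annular pipettes, triangular pillar rows periodic across the device
width), rendered as frozen DPD particles filling one thermostat-cutoff
of the solid plus bounce-back reflection at the SDF zero level
(crossing particles retrace their path with negated velocity), which
together enforce no-slip. Pressure-driven flow is a uniform body force
(`g = ∇P/ρ`) — the standard periodic-cell stand-in for pressure
boundaries; 0.67 Pa/µm maps to `g ≈ 0.194` per particle.

*Aspiration.* The physical protocol (0 → 117.72 Pa at 3.27 Pa/s) spans
36 s of wall-clock time — about 10⁹ DPD steps, unreachable for any
simulation including the original; the ramp is therefore a quasi-static
staircase whose level count and steps per level are artifact
parameters, with the physical rate retained as metadata. Suction is a
body force on cell particles inside the pipette bore, rescaled each
chunk so the total equals `ΔP·πR_p²` (the pressure force on the
aspirated tongue). `L_p` is the maximal membrane-vertex penetration
past the mouth plane; `L_p0` is measured at the first (baseline) level.

*Transit.* One constriction period (pillar row periodic across the
device width, flow direction periodic over the row spacing, depth
walled), fluid pre-equilibrated, cell inserted upstream; velocity is
travelled centroid distance over time, with a stuck detector (windowed
centroid advance below tolerance).

*Analysis.* The Theret half-space punch model gives
`E = 3Φ_p/(2π) × slope(ΔP vs L_n)` over the linear (lower) part of the
ramp; `Φ_p = 2.1` by default and exposed, since the wall function is
geometry-dependent. Creep at constant pressure is fitted as
`L_n(t) = L_∞(1 − e^{−t/τ})`, and the effective viscosity follows the
Kelvin–Voigt correspondence of the punch solution, `η = Eτ` — monotone
in `τ` at fixed `E`, vanishing as `τ → 0`.

# Parameters (defaults)

| parameter | value (sim) | physical | note |
|---|---|---|---|
| fluid density | 3 µm⁻³ | — | typical DPD range 3–4 |
| dt | 10⁻³ | 33 ns | stability limited by `κ_fil` |
| k_BT | 1 | 1.15×10⁻¹⁸ J | filament-block energy unit |
| filament length | 4.0 | 4 µm | |
| `N_fil` | 3.5 µm⁻³ | — | sweep range 1.25–4 |
| `κ_fil` | 8×10⁴ | 0.092 N/m | |
| `κ_bend` | 350 | 4.0×10⁻¹⁶ J | |
| `N_CL` | 0.525 µm⁻³ | — | |
| `κ_CL` | 8×10³ | 0.0092 N/m | |
| `κ_CL/fil` | 550 | 6.3×10⁻¹⁶ J | θ₀ = π/2 |
| `k_tor` | 470 | 4.7×10⁻¹⁶ J | φ₀ = constructed |
| WLC `p` | 0.00141 | 1.41 nm | |
| cell `l_max` | 3.0 | 3 µm | stiffness handle |
| nucleus `l_max` | 1.2 | 1.2 µm | lamina handle |
| cell `k_b` | 65 | 6.1×10⁻¹⁸ J | *membrane-row unit* |
| nucleus `k_b` | 250 | 2.6×10⁻¹⁷ J | *membrane-row unit* |
| `k_a`/`k_v` (cell) | 10⁴ / 1.5×10⁴ | — | nucleus `k_a` 5×10³ |
| `γ^C` | 30 | 1.15×10⁻⁹ N s/m | `γ^T = 3γ^C`; fixes the time unit |

The membrane bending rows imply a different energy unit
(≈ 9.4×10⁻²⁰ J) than the filament block (≈ 1.15×10⁻¹⁸ J); no
consistency is forced — sim-unit values are authoritative and both
mappings are configurable.

# What the synthetic/reduced-scale fixtures do and do not establish

The test fixtures (6 µm "mini-cell" with a ~320-vertex surface, one
constriction period, 6³–10³ µm³ network boxes) exercise every code path
at desk scale. A green fixture test establishes correctness of forces
(exact gradient checks), conservation laws, thermostat calibration,
binding-rule invariants and determinism. It does **not** establish the
calibrated whole-cell response: aspiration curves matching the
measured modulus, transit-velocity comparisons across devices, the
nucleus-removal velocity ratio and the Fig-4-style parameter sweeps
require cell-scale ensembles (≥ 10⁵ particles, ≥ 5×10⁵ steps, 16 cells
× 4 rotations) and are cluster-scale by the acceptance criteria's own
scoping. Reduced-scale topology statistics also shift with box size:
linked-vertex fractions grow as surface/volume grows (mini-cell ≈ 0.4
vs 0.21/0.26 at full scale), and the per-filament CL spread in a 10³
µm³ box (± ~1.8) exceeds the full-scale ± 1.1.

# Numerical choices

* **Verlet pair lists** (skin 0.3, rebuild at half-skin displacement)
  over cell lists; a brute-force path covers boxes smaller than three
  cutoffs. Neighbour search is verified against an O(N²) oracle.
* **Instability guards**: a per-step displacement above the largest
  cutoff aborts with the particle index; overstretched WLC edges,
  degenerate dihedrals, zero-length bonds and coincident pairs raise
  identified errors.
* **Determinism**: the engine RNG is seeded per call; all R-level
  stochastic passes run under `set.seed` with derived sub-seeds. One
  seed, one thread → bit-identical trajectories (tested).
* **Bounce-back** finds the SDF crossing by bisection (25 iterations)
  and mirrors the remaining path; particles deeper than one cutoff
  inside a wall abort.
* **Chunked binding**: binding/unbinding passes between dynamics
  chunks (200 steps) rather than every step; with the low-friction CL
  choice the sampling interval is well below the CL position
  decorrelation time, so the converged topology is insensitive to the
  chunk size.
* **Near-wall layer**: continuum comparisons (Poiseuille) exclude
  roughly one cutoff next to walls, where frozen-particle layering
  perturbs the profile — standard DPD practice.

# Known limitations

* No cytoskeleton reorganisation during experiments (bond topology
  frozen after assembly; the formation-time Bell kinetics are far
  slower than device transit times).
* Global (not per-triangle) area constraint; no thermal-undulation
  analysis.
* Pillar size and pipette wall geometry are not constrained by the
  source experiments; defaults (equilateral side = gap, `R_p = 3 µm`,
  1 µm wall) are exposed as configuration.
* Body-force driving stands in for pressure boundaries; only one
  obstacle period is simulated, not the ten-row device.
* The aspiration staircase is quasi-static; rate-dependent effects of
  the physical ramp are outside scope.
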