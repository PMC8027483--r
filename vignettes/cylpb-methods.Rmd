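---
title: "Methods: the cylindrical NLPB model behind cylpb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cylindrical NLPB model behind cylpb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cylpb` models the ionic double layer around microtubules (MTs) with the
nonlinear Poisson–Boltzmann (NLPB) equation in cylindrical symmetry. This
vignette records the model, its assumptions, the numerical scheme, and the
design decisions that were genuinely open — in enough detail that a reader
can judge what a passing test suite does and does not establish.

## Model and assumptions

The MT is split into independent infinite-cylinder problems sharing one
buffer: the lumen wall seen from inside (R = 8.4 nm, σ = −0.025 C/m²,
from −5 e per dimer), the outer wall seen from outside (R = 12.5 nm,
σ = −0.083 C/m², from −25 e per dimer), and a C-terminal tail (CT)
modelled as an infinite cylinder of radius 0.5 nm with σ = −0.140 C/m²
(−11 e spread over a 4 nm lateral area). Surface charge densities follow
from the 13-protofilament lattice with an 8 nm axial dimer repeat; they
are computed, not hard-coded, so geometry overrides propagate.

Assumptions inherited from mean-field PB theory: point-like ions apart
from a hard distance of closest approach, no ion–ion correlations, a
monovalent symmetric electrolyte (KCl), fixed uniform surface charge (no
charge regulation; pH 7 charges), and infinite cylinders (the CT's finite
4 nm length and the helical lattice are ignored). The independent-cylinder
approximation means CT double layers are never geometrically clipped
against the outer-wall layer; at low ionic strength these regions overlap
heavily and the parallel-conductor picture over-counts volume. These are
modelling choices of the underlying analysis that the package reproduces
deliberately.

Three refinements beyond textbook PB:

* **Stern layer.** The annulus of one hydrated-K⁺ radius
  (`d_stern = 0.33` nm) next to each charged surface carries no ions and
  is excluded from the solved domain. The surface charge enters through
  the Gauss-law flux at the outer Helmholtz plane (OHP):
  `dV/dr|_(R±d) = ∓ σ/(ε_r ε_0) · R/(R ± d)`. The potential drop across
  the Stern annulus itself is never computed; every observable is defined
  from the OHP outward (or inward, for the lumen).
* **Booth dielectric saturation.** `ε_BE = 1.8 + (ε_w − 1.8) L(0.08 E)`
  with E in mV/Å (1 V/m = 10⁻⁷ mV/Å) and `L(x) = 3(coth x − 1/x)/x`.
  For cylinders the surface-geometry correction to the local permittivity
  is negligible, so the zero-field value is bulk water, ε_w = 78.5 at
  298 K.
* **Ion-crowding decrement.** `ε = ε_base(1 − ρ + 3αρ)/(1 + ρ/2)` with
  `α = ε_K/(2 ε_base)` and `ρ = c_K/(c_K + c_max)`, `c_max = 15.9` M.
  In the full model (the default) the Booth value is the base, so both
  effects compose; `permittivity_model()` also exposes each effect alone
  and a constant-ε mode, which is what `compare_model_variants()`
  contrasts.

The ε_r in the flux boundary condition is the converged local
permittivity at the OHP node, updated every outer sweep. The underlying
analysis does not say which ε its boundary conditions used;
self-consistency is the only reading under which the discrete Gauss law
stays exact, so that is what the package does.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `d_stern` | 0.33 | nm | hydrated K⁺ radius; swap for other cations |
| `c_max` | 15.9 | M | K⁺ packing limit in the crowding term |
| `eps_w` | 78.5 | — | bulk water at 298 K |
| `eps_K` | 5 | — | hydration-shell permittivity of K⁺; **not fixed by the source analysis** (see below) |
| `lambda_cation`, `lambda_anion` | 7.352e−3, 7.634e−3 | S·m²/mol | limiting molar conductivities of K⁺ and Cl⁻ |
| binding threshold | −k_B·T/e = −25.68 mV | V | exact thermal voltage rather than the rounded −25 mV; configurable in every observable |
| `n_grid` | 2000 | — | radial nodes; see refinement results |
| `r_max_factor` | 40 | λ_D | exterior truncation radius |

ε_K deserves emphasis: the crowding formula needs the cation's effective
permittivity and the source analysis never states the value it used. The
package defaults to 5, a representative saturated-hydration-shell value,
records it in every output header, and leaves it configurable. At the OHP
of the outer wall at 160 mM the difference between ε_K = 5 and ε_K = 10
moves the local ε by a few units and the potential by well under the
model's other uncertainties; sensitivity is cheap to probe by re-running
any scenario with a different `permittivity_model()`.

The molar conductivities are stored in SI S·m²/mol. The values quoted in
the molar-conductivity literature for K⁺ and Cl⁻ are 73.52 and
76.34 S·cm²/mol; a reader will occasionally meet them mislabelled a
thousandfold, so the package keeps the unit in the field name.

## Numerical scheme

**Discretization.** Conservative finite volumes on a radial grid
exponentially clustered toward the charged surface: node positions follow
`s(t) = S·(e^{at} − 1)/(e^a − 1)` with clustering strength `a = 8`, so at
the default 2000 nodes the first cell is ~λ_D/19000 and the last ~0.16 λ_D.
One grid resolves both the sub-nanometre layer at 500 mM and the ~100 nm
tail at 10 μM. Fluxes `r ε dV/dr` are evaluated at cell faces; summing the
discrete equations telescopes to the boundary fluxes, so exterior
screening completeness and lumen electroneutrality hold to solver
tolerance by construction — the corresponding tests check the *integrals*,
which also exercises the quadrature.

**Boundary conditions.** Exterior problems close with a Robin condition
matching the linearized K₀ tail, `dV/dr = −(V/λ_D)·K₁(x)/K₀(x)` at
`r_max = R + d + 40 λ_D`; this permits smaller domains than a hard
Dirichlet zero and is what makes doubling `r_max_factor` move bound-layer
observables by < 10⁻⁴ relative. Interior problems impose symmetry at the
axis; the 1/r singularity never appears because the axis cell integrates
`r dr` analytically. Modified Bessel ratios are always formed from
exponentially scaled `besselI`/`besselK`, so planar-limit oracle cases
with R = 1000 λ_D evaluate without overflow.

**Iteration.** Damped Newton on the nonlinear residual (tridiagonal
Jacobian, Thomas solve, step capped at 5 thermal voltages, backtracking
line search) inside an outer fixed-point loop that recomputes ε(E, c⁺)
with under-relaxation 0.5. Stops: max |ΔV| < 10⁻⁸ V_t (Newton), max
relative ε change < 10⁻⁶ (outer). The initial guess is the analytic
linearized solution clipped to ±8 V_t; if Newton stalls, the solver ramps
the surface charge in quarters, warm-starting each stage (in practice the
ramp is not needed for any scenario in the study range). Runs are
deterministic and bit-reproducible; there is no randomness anywhere in
the package.

**Verified behaviour.** Richardson estimates over (n, 2n, 4n) grids give
convergence order ≈ 2.0 for all three geometries; the Grahame planar
limit is met to < 0.5%; the nonlinear-to-linear deviation decays cubically
in σ (sinh is odd, so the leading correction is O(σ³) — a sharper check
than first-order agreement); the Boltzmann product c⁺c⁻ = c_s² is exact
by construction. Degenerate inputs: σ = 0 returns the zero solution
immediately; T ≤ 0, c_s ≤ 0, ρ ∉ [0,1), negative fields and Stern radii
exceeding the lumen radius are rejected at the type boundary.

## Observables: the open design choices

**Binding criterion.** Ions at potentials below −k_B T/e are bound. The
exact −25.68 mV is used, not the rounded −25 mV; the threshold is an
argument everywhere, so the ±1 mV sensitivity is directly computable.

**Extent reference.** Exterior bound-layer extents are measured from the
OHP to the interpolated crossing radius. For the lumen the extent is
measured from the physical wall and saturates at the lumen radius when
the entire lumen is bound, which is the natural reading of a "distance
from the surface to the thermal voltage" that has a geometric maximum.

**CT bound-ion attribution.** The 13 infinite CT cylinders stand in for
26 discrete 4 nm tails per 8 nm lattice repeat. When converting the CT
cylinder's per-length bound charge to a per-heterodimer number the package
attributes the tail-bearing 4 nm of effective cylinder once per dimer
(`ct_bound_length_per_dimer`). The alternative — 2 × 4 nm, i.e. the full
8 nm of effective cylinder per dimer — double-counts ions that the
infinite-cylinder idealization places in the tail-free gaps; with the
4 nm convention the computed net complex charge sits on a flat
≈ −15 e plateau at low salt, which is the behaviour the net-charge
bookkeeping is meant to capture. The protein charge itself always counts
both tails (−52 e per dimer: −5 − 25 − 2×11).

**Mean conductivity and its normalization.** Local conductivity is
σ(r) = λ_K c⁺(r) + λ_Cl c⁻(r); both species count, since the bound region
is defined by potential, not by species. The complex's outer radius is
the thermal-voltage crossing radius of the outer wall, r_cross, and the
normalization area is A_norm = π r_cross² (the CT annuli add conductance,
as 13 parallel conductors, but no normalization area). For the lumen the
package defaults to counting *all* lumen electrolyte
(`lumen_region = "fluid"`): the lumen lies inside the complex whatever
the binding status of its ions, and a nanowire's conductance counts all
mobile carriers inside it. The stricter alternative
(`lumen_region = "bound"`), which zeroes the lumen term once the wall
potential is shallower than the threshold, is one flag away. The two
readings coincide below ~10 mM (the whole lumen is bound there) and
diverge at physiological ionic strength, where the choice shifts the
crossover concentration by tens of mM — this is the single most
consequential ambiguity in the conductivity bookkeeping, which is why
both are implemented.

## What the scenario generator emulates — and does not

`validation` scenarios are parameterized physical configurations, not
random draws: this is a deterministic mean-field model with no noise
process, so "synthetic data" means the canonical scenario grid (10 μM,
100 μM, 1, 10, 100, 160, 500, 501 mM across lumen / outer wall / CT) plus
closed-form oracle cases (planar Grahame, linear-regime Bessel,
refinement suites). Passing tests therefore establish that the solver
solves the stated equations correctly and stably — they say nothing about
whether mean-field PB with these parameters describes a real microtubule.
In particular, real systems add ion–ion correlations, finite CT length
and flexibility, charge regulation, and surface conduction corrections
that no test here probes.

## Problem sizes

The default production grid is 2000 nodes (40 λ_D exterior domains). The
test suite runs most scenarios at 400–1500 nodes, where every stated
tolerance already holds with an order of magnitude to spare (the 2000 →
4000 node change moves the 160 mM OHP potential by ~6×10⁻⁷ relative);
refinement checks use 300–1600 nodes, and crossover bisections in the
tests use 1200-node grids with the bracket [10, 500] mM and relative
tolerance 10⁻³. The full suite solves a few hundred NLPB problems in
roughly half a minute on one CPU.

## Known limitations

* Axial conductivity only; radial transport is out of scope.
* Monovalent symmetric electrolytes only; divalent ions are poorly served
  by mean-field PB anyway.
* No finite-length or lattice geometry for the CTs; no clipping of
  overlapping bound regions.
* ε_K is an assumed constant, not a fitted or measured value.
* The Stern layer corrects ion size only at the wall, not throughout the
  solution (no size-modified PB).
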