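---
title: "Grid-based Brownian dynamics with a Debye-Hückel long-range tail: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based Brownian dynamics with a Debye-Hückel long-range tail: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridbd)
```

This vignette is the package's own account of its science: the propagation
model and its assumptions, the interaction scheme and its one deliberate
discontinuity, the virial-coefficient machinery, the tunable parameters, the
numerical choices, and what the synthetic test systems do and do not probe.
Units everywhere: Å, ps, kcal/mol, elementary charge *e*, Kelvin
(k~B~T ≈ 0.596 kcal/mol at 300 K).

## Propagation model

Solutes are rigid bodies — atoms fixed in a body frame whose origin is the
center of geometry — with a position and a unit quaternion per solute.  The
full Ermak–McCammon translational propagator couples all solutes through the
configuration-dependent diffusion tensor and contains a divergence term that
drifts solutes toward regions of high mobility.  Solving it requires a
Cholesky factorization of the 3N×3N tensor at every step, which is what makes
many-protein hydrodynamics expensive.  We adopt the mean-field reduction: the
tensor is replaced by a scalar short-time coefficient that depends only on the
solute's *local volume fraction* φ~i~,

r~i~(t+Δt) = r~i~(t) + D~t~^short^(φ~i~)/k~B~T · F~i~ Δt + **R**~i~,

with ⟨**R**~i~⟩ = 0 and per-component variance 2 D~t~^short^(φ~i~) Δt.  Because
the replacement is position-independent within a step, the divergence term of
the full propagator vanishes identically — the reduction is exact given the
mean-field ansatz, not an extra approximation.  Rotation uses the same
structure: a drift D~r~^short^/k~B~T · τ~i~ Δt plus an isotropic Gaussian
rotation vector of per-axis variance 2 D~r~^short^ Δt, composed onto the
quaternion and renormalized.

φ~i~ is the occupied fraction of a sphere of radius R^cut^ around solute *i*:
neighbors are spheres of their Stokes radius; fully contained neighbors
contribute their volume v = 4/3·π·σ^stokes³, partially contained ones the
exact sphere–sphere lens volume.  The central solute's own volume is
*excluded* by default: the published definition ("the sum of the volumes of
the solutes within R^cut^") is ambiguous on this point, the exclusion keeps
φ = 0 at infinite dilution (so D → D₀ exactly), and a toggle
(`include_self_phi`) is provided; at the densities of interest the difference
is a near-constant offset v/V~local~.

The φ-dependent coefficients are pinned, auditable transcriptions of the
standard hard-sphere suspension results: the Tokuyama–Oppenheim short-time
translational form D~t~^short^/D₀ = 1/(1+H(φ)) with
H = 2b²/(1−b) − c/(1+2c) − bc(2+c)/((1+c)(1−b+c)), b = √(9φ/8), c = 11φ/16
(domain φ < 0.64), and the Cichocki et al. rotational virial series
D~r~^short^/D₀ = 1 − 0.631 φ − 0.726 φ², which includes lubrication and
two-/three-body mobility contributions.  Infinite-dilution coefficients come
from Stokes–Einstein with the Stokes radius and a configurable solvent
viscosity (default 0.89 cP, water at 300 K).

## Interaction scheme

The pair free energy is a sum of four gridded terms: charge-on-grid
electrostatics (with the ½ double-counting factor, evaluated in both
directions), electrostatic desolvation (squared charges against the partner's
desolvation grid), non-polar desolvation (SASA-weighted), and an
inverse-power soft-core repulsion.  Grids are node-centered uniform cubic
scalar fields in the owner's body frame; sources are interpolated
trilinearly.  Each grid carries an isotropic cutoff equal to its
inscribed-sphere radius: a source beyond the cutoff contributes exactly zero.

**The hybrid electrostatic rule.**  Let R~switch~ be the smaller of the two
electrostatic grids' inscribed-sphere radii.  For center-to-center distance
d < R~switch~ the gridded electrostatic term is used (with the per-charge
cutoff); for d ≥ R~switch~ it is *replaced* by the analytic Debye-Hückel
net-charge term

w(r) = z~i~ z~j~ e² exp(−κ(r−a)) / (4π ε₀ ε~r~ r (1+κa)),   r ≥ a = a~i~+a~j~,

truncated at a pair cutoff (default 4× the electrostatic grid side, rescaled
to half the box when larger, to avoid self-image interactions).  Grid term
and tail are never both applied to a pair: substitution, not addition,
avoids double counting.  The DH sphere radii default to the Stokes radii.

This scheme has a known seam.  Just inside R~switch~ a sizeable fraction of
the partner's charges already lies beyond the isotropic cutoff and
contributes nothing, so the energy (and force) jumps at the switch radius —
for the 6 Å charge shells of the test spheres the step is roughly half of
w(R~switch~).  `switch_discontinuity()` measures the jump along any
direction.  A boundary interpolation that would smooth it is deliberately
not implemented; deep inside the grid regime (all sources within the
cutoff) the gridded energy of the test spheres agrees with the analytic
w(r) to ~2%, the small residue being the different contact conventions
(sphere radius a₀ in the grid potential vs. a = 2a₀ in the pair form:
exp(−κa₀)(1+2κa₀)/(1+κa₀) ≈ 0.98 at 5 mM).

Forces and torques are central finite differences of the pair energy:
translations of ±δ along the lab axes (force on one solute; the pair energy
depends only on the relative displacement, so the partner's force is equal
and opposite), rotations of ±δθ about lab axes through each center
(defaults δ = 0.1 Å, δθ = 0.01 rad — small enough that the O(δ²) error is
far below the stochastic forces, large enough to stay clear of grid
interpolation noise).  In the pure-DH regime the energy is radial, so one
radial difference suffices and torques vanish.

## Second osmotic virial coefficients

The long-range B22 quantifies how much of the pair interaction the model
captures.  Three routes are implemented and cross-checked:

1. **Closed form** (`b22_analytic_longrange`): expand the Mayer function
   exp(−w/k~B~T) − 1 to second order in w/k~B~T and integrate
   −½(...)·4πr² dr analytically from the lower bound `lb` to infinity.  For
   a general lb and κ > 0,

   B22 = 2πβC e^{−κ(lb−a)} (lb/κ + 1/κ²)/(1+κa) − πβ²C² e^{−2κ(lb−a)} / (2κ(1+κa)²),

   with C = z~i~z~j~e²/(4πε₀ε~r~) and β = 1/k~B~T; at the canonical
   lb = a + 1/κ the exponentials become 1/e and 1/e².  The expansion is
   flagged once |w(lb)|/k~B~T exceeds 0.5 (for ±10 e spheres at 5 mM it is
   not trustworthy — the full integral diverges near contact).
2. **Quadrature** (`b22_quadrature`): adaptive 1-D integration of either the
   full Mayer integrand or its second-order expansion; the closed form is
   unit-tested against it at 0.1%.
3. **Lattice protocol** (`b22_lattice`): one sphere fixed at the center of a
   400 Å cube, the other visiting a 100³ vertex lattice (4 Å spacing, vertex
   offsets symmetric about the center so no vertex sits at r = 0); vertices
   closer than contact (12 Å) are excluded, the pair energy is evaluated at
   every remaining vertex through the same grid/DH machinery the simulator
   uses, and B22 = −½ Σ~r≥lb~ (e^{−E/kBT}−1) ΔV.  Error bars follow the
   resampling protocol: 100 random subsets of 10⁵ vertices, each rescaled to
   the full integration volume — the only subset estimator whose mean is
   unbiased.  Orientations stay fixed during the scan (the test spheres are
   isotropic by construction).

Design choices worth stating: the lower bounds quoted as "1/κ, 2/κ" are
*contact plus* n Debye lengths (lb = a + n/κ), matching the closed form's
derivation; and the lattice scan applies **no** DH distance cutoff (the
4-grid-sides cutoff is a simulation economy — imposing it inside the 400 Å
box would discard ~7% of the integrand and misrepresent what the grids-plus-
tail model captures).  Absolute values are reported in Å³; cross-method
comparisons are unit-free ratios.

## Solution observables

g(r) is the standard minimum-image pair histogram normalized by ideal-gas
shell counts (default 1 Å bins, range box/2).  S(q) is the Fourier transform
S(q) = 1 + 4π n~p~ ∫ h(r) sin(qr)/(qr) r² dr, trapezoidal on the histogram
grid, truncated at the histogram range, with an optional half-cosine taper
over the outer half of the range to damp truncation ringing; q = 0 uses the
sinc limit, giving the osmotic-compressibility combination.  The truncation
matters: S(q→0) is only meaningful when h(r) has decayed within box/2, which
sets the box sizes used in the tests.  The oblate-ellipsoid form factor
averages the sphere amplitude over the angle between q and the symmetry
axis with sin α weight (the isotropic orientational measure; the degenerate
a = b case reduces to the homogeneous-sphere form factor, and P(0) = 1
exactly).  Normalized intensity is the pointwise product P·S on a shared q
grid.  Long-time self-diffusion is the least-squares MSD slope over a
configurable lag window (default 10–50% of the trajectory) divided by 6,
using image-count-unwrapped coordinates; g(r) convergence follows the
20-segment protocol, with a count-weighted per-segment deviation statistic
so that nearly-empty small-r bins do not drown the signal.

## Synthetic test systems

`make_sphere_system` builds the self-contained test pair: 180 point charges
of z/180 e each on a 6 Å shell (golden-angle spiral, iteratively recentered
so the center of geometry is exactly the origin; nearest-neighbor spacing is
~4× more uniform than random placement), Stokes radius 6 Å, an analytic
screened-Coulomb sphere grid (`sphere_dh_grid`, the exact exterior solution
a linearized Poisson–Boltzmann solver would produce for this charge
distribution, interior filled with the contact value), and an inverse-power
soft-core grid (default n = 6, σ = atomic radius, capped at 100 kcal/mol so
finite-difference forces stay finite and smooth — the cap is the "hard
overlap sentinel" also used by the engine when charged solutes without grids
approach below contact).

What these systems emulate: the exact geometry of the published two-sphere
virial benchmark, and the low-/high-ionic-strength conditions (5 mM with
1/κ = 43.2 Å under this package's constants — the published rounding is
43.1/43; 300 mM with 1/κ = 5.6 Å).  What they do not emulate: anisotropic
charge distributions, desolvation terms (their parameterization lives in
force-field references, and the grids default to absent), internal
flexibility, and solvent-structure effects.  Passing tests therefore
validate the *machinery* — grids, switching, propagation, estimators — not
the force field's fidelity for real proteins.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| timestep Δt | 0.5 | ps | published production value; stochastic step ≪ solute size |
| record interval | 500 | ps | published recording cadence |
| temperature | 300 | K | published simulation temperature |
| ε~r~ | 78.5 | — | water; see note below |
| viscosity | 0.89 | cP | water at 300 K (Stokes–Einstein D₀) |
| DH pair cutoff | 4× grid side, ≤ box/2 | Å | tail negligible beyond; avoids self-images |
| R^cut^ (local volume) | 4× grid side, ≤ box/2 | Å | published rule |
| equilibration fraction | 0.2 | — | published 1 μs of 5 μs |
| δ, δθ | 0.1, 0.01 | Å, rad | finite-difference steps (unpublished; see above) |
| soft-core n, ε, cap | 6, 1, 100 | —, kcal/mol | inverse-power form; smooth contacts |
| g(r) bin width | 1 | Å | resolves the first peak at protein scales |
| q grid | 0.05–4 | nm⁻¹ | small-angle scattering window |

**The ε~r~/temperature note.**  The source conditions quote a 43.1 Å Debye
length at 5 mM and 5.5 Å at 300 mM without stating ε~r~ or whether κ uses
298 or 300 K.  With SI constants at T = 300 K, ε~r~ = 78.5 gives 43.154 Å
and 5.571 Å; no single (ε~r~, T) reproduces both quoted values to ±0.05 Å
(their ratio would have to be √60 = 7.746, but 43.1/5.5 = 7.84).  We keep
the standard ε~r~ = 78.5 at 300 K and regard the quoted values as rounded
to ~0.1 Å.

## Numerical choices and degenerate inputs

* Trilinear interpolation is exact on nodes; points outside a grid's
  bounding box are an error — cutoff logic must run first, and the cutoff ≤
  inscribed radius invariant guarantees interpolability.
* Minimum-image wrapping maps components to the half-open interval
  [−side/2, side/2); ties at exactly side/2 go to the negative image.
* dh_pmf returns +Inf below contact (hard overlap).  The engine substitutes
  a finite contact value plus a steep linear ramp (10³ kcal/mol/Å) so the
  finite-difference force is a large, finite restoring force; a genuinely
  non-finite force or torque aborts the run naming the pair.
* φ is clamped to [0, 0.6375] before evaluating the Tokuyama form (domain
  φ < 0.64); the user-facing functions reject out-of-domain φ instead.
* Quadrature to infinity relies on the exponential decay of w; hard cores
  are handled by integrand breakpoints supplied by the caller.
* The pair search is a plain O(N²) minimum-image scan with an early
  distance skip — at N ≤ 250 the finite-difference energy evaluations
  dominate the cost, so cell lists would add bookkeeping without measurable
  gain.
* All randomness (placement, orientations, noise, subset draws) flows from
  one seed through R's RNG in a single-threaded engine; the same seed
  reproduces a trajectory bit for bit, which the suite asserts.
* Orientations are unit quaternions (w, x, y, z), renormalized every step;
  initial orientations are uniform on SO(3), initial positions random
  non-overlapping placements (error after 10⁴ failed tries per solute,
  suggesting a larger box).
* Recorded energies are instantaneous sums at the recording step, not
  interval averages; per-term sums equal the recorded total to 10⁻⁶.

## Problem sizes used by the test suite

The published protein-scale experiments (250 BSA/HEWL molecules, 5–10 μs)
are not desk-scale; the suite validates the same machinery on scaled
conditions chosen once: free-diffusion D₀ recovery uses 200 solutes ×
5 000 steps with small-lag MSD fitting (estimator SE ≈ 0.8%, against a 2%
band); Boltzmann sampling of the DH pair distribution uses one +5/+5 pair
over 2×10⁶ steps thinned to ~500 quasi-independent samples (χ² against
r² e^{−w/kBT}); the qualitative DH effects use 25 spheres of +10 e at 5 mM
in a 160 Å box for 2×10⁵ steps (0.1 μs) — large enough that h(r) decays
inside box/2, strongly coupled enough (βw ≈ 2 at mean spacing) that the
S(q→0) suppression, the slowdown of long-time self-diffusion, and the
short-range depletion of g(r) when the tail is switched on are all far
outside noise.  The full lattice protocol runs at its published size
(400 Å box, 10⁶ vertices).

## Known limitations

* Rigid bodies only; no internal degrees of freedom.
* Mean-field hydrodynamics: no pair-level mobility coupling, no
  hydrodynamic torque-force coupling; short-time coefficients are
  hard-sphere results applied at the local φ.
* The grid/DH switch is discontinuous for extended charge distributions
  (measured by `switch_discontinuity`); energy conservation is not a BD
  invariant so the seam mainly matters for strongly charged, strongly
  anisotropic solutes near the grid boundary.
* Desolvation terms are implemented but ship without a parameterization;
  their grids must come from an external source.
* The closed-form B22 is a second-order expansion: for |w(lb)|/k~B~T ≳ 1
  (±10 e at 5 mM) it is flagged unreliable, mirroring the divergence of the
  full integral for those systems.
* Cubic grids only — efficient for globular solutes, wasteful for elongated
  ones.
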