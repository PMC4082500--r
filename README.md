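# gridbd

Rigid-body Brownian dynamics (BD) of many-macromolecule solutions with
pairwise forces from precomputed interaction grids and an analytic
Debye-Hückel (DH) long-range electrostatic tail.

## The problem

BD simulations of protein solutions keep atomic detail but treat each
macromolecule as a rigid body in continuum solvent; for speed, the
intermolecular interaction terms — electrostatics, electrostatic
desolvation, non-polar desolvation, and a soft-core repulsion — are
precomputed on cubic grids centered on each solute.  Finite grids truncate
the long-range electrostatic potential: at low ionic strength (Debye
length 1/κ ≈ 43 Å at 5 mM) or for highly charged proteins, the grid would
have to be impractically large.  Beyond the grid boundary, however, the
potential of a globular solute is nearly centrosymmetric, so a solute pair
can be treated as two Debye-Hückel spheres with net charges *z_i*, *z_j*
and contact distance *a = a_i + a_j*:

    w(r) = +Inf                                              r < a
    w(r) = z_i z_j e² exp(-κ(r-a)) / (4π ε0 εr r (1 + κa))   r ≥ a

`gridbd` implements this hybrid scheme: gridded interactions while the
partner sits inside the grid's inscribed sphere, the analytic DH tail
beyond it.  Positions and orientations are propagated with a mean-field
Ermak–McCammon step in which the diffusion tensor is replaced by
volume-fraction-dependent short-time coefficients (Tokuyama for
translation, Cichocki et al. for rotation), with the local volume fraction
φ_i measured in a sphere of radius R_cut around each solute.

The package also ships the validation machinery used to probe the scheme:

* **Second osmotic virial coefficients** for a pair of uniformly charged
  "fullerene-like" spheres (radius 6 Å, 180 point charges): the
  closed-form long-range B22 (second-order expansion of the Mayer
  function), 1-D adaptive quadrature, and the 3-D lattice-integration
  protocol (one sphere fixed in a 400 Å box, the other visiting 100³
  lattice vertices, with random-subset error bars).
* **Solution observables** from trajectories: radial distribution function
  g(r), structure factor S(q) by Fourier transform of h = g − 1 (S(q→0)
  is the osmotic-compressibility limit), oblate-ellipsoid form factor
  P(q), normalized intensity I/(A n_p) = P·S, g(r) convergence
  diagnostics, and long-time self-diffusion from MSD slopes.

It is aimed at researchers studying concentrated protein solutions
(small-angle scattering, self-diffusion, weak protein–protein
interactions) who need the long-range electrostatics of low-ionic-strength
conditions without giant grids.

## Worked example

Two +5 e spheres at 5 mM ionic strength, 300 K: how much of the analytic
long-range B22 does a 100 Å grid plus the DH tail recover?

```r
library(gridbd)
solv <- solvent_model(300, 78.5, ionic_strength = 0.005)
solv
#> <solvent_model> T = 300 K, eps_r = 78.5, kappa = 0.023173 1/A (1/kappa = 43.2 A)

lb  <- 12 + 1 / solv$kappa        # contact + one Debye length
ana <- b22_analytic_longrange(dh_pair(5, 5, 12, solv), lb = lb)
ana
#> <B22 analytic> 1.18433e+06 A^3 (lb = 55.15 A)

sys <- make_sphere_system(5, 5, solv, grid_side = 100)
lat <- b22_lattice(sys, solv, lb = lb, use_dh = TRUE, seed = 1)
lat
#> <B22 lattice> 1.1506e+06 A^3 (lb = 55.15 A; subsets: 1.15077e+06 +- 7.5e+03)

100 * lat$value / ana$value
#> [1] 97.2
```

The lattice integration (10⁶ pair energies, Boltzmann-weighted Riemann
sum over all vertices at least `lb` from the fixed sphere) recovers 97% of
the closed-form value; without the DH tail the same 100 Å grid recovers
exactly 0 at this lower bound, because the inscribed-sphere switch radius
(50 Å) lies inside `lb`.  The subset mean ± SD comes from 100 random
subsets of 10⁵ vertices, each rescaled to the full integration volume.

A small command-line driver is installed as `exec/gridbd`
(subcommands `b22`, `simulate`, `scatter`, `diffusion`, `make-testsys`,
`make-grid`), e.g.

```sh
gridbd b22 --z1 1 --z2 1 --ionic-strength 0.005 --lb onedebye --seed 1
```

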