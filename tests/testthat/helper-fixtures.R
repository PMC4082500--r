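# Shared fixtures, built in code at test time.

# study-condition solvents
solv5 <- solvent_model(300, 78.5, ionic_strength = 0.005)
solv300 <- solvent_model(300, 78.5, ionic_strength = 0.3)

# a small deterministic grid with smoothly varying values
ramp_grid <- function(n = 5, spacing = 2, kind = "electrostatic",
                      f = function(x, y, z) 0.3 * x - 0.1 * y + 0.05 * z + 1) {
  origin <- rep(-(n - 1) / 2 * spacing, 3)
  ax <- origin[1] + (seq_len(n) - 1) * spacing
  vals <- array(0, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    vals[i, j, k] <- f(ax[i], ax[j], ax[k])
  potential_grid(vals, origin, spacing, kind = kind)
}

# point-free solute (no atoms off-center, no grids): a bare Brownian sphere
bare_sphere <- function(radius = 6, charge = 0) {
  solute(atom_set(matrix(0, 1, 3), charges = charge, radii = 1),
         stokes_radius = radius, net_charge = charge)
}

# a minimal hand-built trajectory object for analysis-code tests
synthetic_traj <- function(positions, box, dt = 1, record_every = 1,
                           energies_total = NULL) {
  nf <- dim(positions)[3]
  N <- dim(positions)[1]
  if (is.null(energies_total)) energies_total <- rep(0, nf)
  en <- data.frame(time = (seq_len(nf) - 1) * record_every,
                   electrostatic_grid = 0, dh_tail = 0, edesolv = 0,
                   npdesolv = 0, softcore = 0, total = energies_total)
  structure(list(times = en$time, positions = positions,
                 images = array(0L, dim(positions)),
                 quaternions = array(rep(c(1, 0, 0, 0), each = N),
                                     c(N, 4, nf)),
                 energies = en, phi = NULL, box = box, solvent = NULL,
                 params = bd_params(dt = dt, n_steps = nf - 1,
                                    record_every = record_every,
                                    equilibration_fraction = 0),
                 species = rep(1L, N), solutes = NULL,
                 D0t = 1, D0r = 1, dh_cutoff = NA_real_, R_cut = NA_real_),
            class = "bd_trajectory")
}
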