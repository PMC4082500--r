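# Domain types shared by all modules.  Conventions: lengths in A, times in ps,
# energies in kcal/mol, charges in units of the elementary charge e,
# temperatures in K.  A solute's "center" is the center of geometry of its
# atoms; orientations are unit quaternions (w, x, y, z) rotating body-frame
# vectors into the lab frame.

#' Create a set of atoms
#'
#' Positions are Cartesian coordinates in Angstrom, partial charges in units
#' of the elementary charge, radii in Angstrom and (optionally) per-atom
#' solvent-accessible surface areas in Angstrom^2.
#'
#' @param positions numeric matrix with one row per atom and columns x, y, z (A).
#' @param charges partial charges (e); recycled if scalar.
#' @param radii atomic radii (A, non-negative); recycled if scalar.
#' @param sasa per-atom solvent accessible surface area (A^2); recycled;
#'   0 means "not a surface atom".
#' @param meta optional data.frame of per-atom metadata (names, residues, ...).
#' @return an object of class `atom_set`.
#' @export
atom_set <- function(positions, charges = 0, radii = 0, sasa = 0, meta = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  rec <- function(x, what) {
    if (length(x) == 1) x <- rep(as.double(x), n)
    if (length(x) != n) stop(sprintf("%s must have length 1 or %d", what, n))
    as.double(x)
  }
  charges <- rec(charges, "charges")
  radii <- rec(radii, "radii")
  sasa <- rec(sasa, "sasa")
  if (any(radii < 0)) stop("radii must be >= 0")
  structure(list(positions = positions, charges = charges, radii = radii,
                 sasa = sasa, meta = meta),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, total charge %.4f e\n",
              nrow(x$positions), sum(x$charges)))
  invisible(x)
}

#' Number of atoms in an atom set
#' @param x an `atom_set`.
#' @return integer count.
#' @export
n_atoms <- function(x) nrow(x$positions)

center_of_geometry <- function(atoms) colMeans(atoms$positions)

#' Create a regular cubic potential grid
#'
#' Node-centered scalar field: the value at array index `(i, j, k)` (1-based)
#' sits at `origin + (i-1, j-1, k-1) * spacing` in the owning solute's body
#' frame.  The cutoff radius may not exceed the radius of the largest sphere
#' inscribed in the grid.
#'
#' @param values 3-d numeric array of node values.  Units by kind:
#'   kcal/mol/e (`electrostatic`), kcal/mol/e^2 (`edesolv`), kcal/mol/A^2
#'   (`npdesolv`), kcal/mol (`softcore`).
#' @param origin position of node (1,1,1) in the body frame (A).
#' @param spacing uniform node spacing (A, > 0).
#' @param kind one of `"electrostatic"`, `"edesolv"`, `"npdesolv"`, `"softcore"`.
#' @param cutoff_radius isotropic per-source cutoff (A); defaults to the
#'   inscribed-sphere radius.
#' @return an object of class `potential_grid`.
#' @export
potential_grid <- function(values, origin, spacing,
                           kind = c("electrostatic", "edesolv", "npdesolv", "softcore"),
                           cutoff_radius = NULL) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  if (any(dim(values) < 2)) stop("grids need at least 2 nodes per axis")
  storage.mode(values) <- "double"
  if (!(spacing > 0)) stop("spacing must be > 0")
  origin <- as.double(origin)
  shape <- dim(values)
  # center of the grid box in the body frame
  center <- origin + (shape - 1) / 2 * spacing
  inscribed <- min((shape - 1) * spacing) / 2
  if (is.null(cutoff_radius)) cutoff_radius <- inscribed
  if (cutoff_radius > inscribed + 1e-9)
    stop("cutoff_radius exceeds the inscribed-sphere radius of the grid")
  structure(list(values = values, origin = origin, spacing = spacing,
                 shape = shape, kind = kind,
                 cutoff_radius = as.double(cutoff_radius), center = center),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid> kind=%s  %dx%dx%d nodes, spacing %.3g A, cutoff %.3g A\n",
              x$kind, x$shape[1], x$shape[2], x$shape[3], x$spacing, x$cutoff_radius))
  invisible(x)
}

#' Number of grid nodes along one axis
#'
#' A grid spanning `extent` Angstrom at a given spacing needs
#' `floor(extent/spacing) + 1` nodes per axis (node-centered layout), e.g.
#' 201 nodes for a 200 A extent at 1 A spacing.
#'
#' @param extent grid side length (A).
#' @param spacing node spacing (A).
#' @return integer node count per axis.
#' @export
grid_node_count <- function(extent, spacing) as.integer(floor(extent / spacing + 1e-9) + 1L)

#' Create a rigid solute
#'
#' Atoms are stored in the body frame with the center of geometry at the
#' origin (input coordinates are recentered).  `effective_charges` is the
#' reduced charge set used for the electrostatic grid terms; its total must
#' agree with `net_charge` to 1e-6 e.
#'
#' @param atoms an [atom_set()] (all atoms; used for soft-core and non-polar
#'   desolvation terms).
#' @param stokes_radius hydrodynamic (Stokes) radius (A, > 0).
#' @param effective_charges optional [atom_set()] holding the effective
#'   charges; defaults to `atoms`.
#' @param net_charge net charge z (e); defaults to the sum of the effective
#'   charges.
#' @param volume solute volume (A^3); default `4/3*pi*stokes_radius^3`.
#' @param grids named list of [potential_grid()]s, names among
#'   `electrostatic`, `edesolv`, `npdesolv`, `softcore`.
#' @return an object of class `solute`.
#' @export
solute <- function(atoms, stokes_radius, effective_charges = NULL,
                   net_charge = NULL, volume = NULL, grids = list()) {
  stopifnot(inherits(atoms, "atom_set"))
  if (!(stokes_radius > 0)) stop("stokes_radius must be > 0")
  cog <- center_of_geometry(atoms)
  atoms$positions <- sweep(atoms$positions, 2, cog)
  if (is.null(effective_charges)) {
    effective_charges <- atoms
  } else {
    stopifnot(inherits(effective_charges, "atom_set"))
    effective_charges$positions <- sweep(effective_charges$positions, 2, cog)
  }
  if (is.null(net_charge)) net_charge <- sum(effective_charges$charges)
  if (abs(net_charge - sum(effective_charges$charges)) > 1e-6)
    stop("net_charge disagrees with the sum of effective charges by more than 1e-6 e")
  if (is.null(volume)) volume <- 4 / 3 * pi * stokes_radius^3
  if (length(grids)) {
    if (is.null(names(grids)) || !all(names(grids) %in%
        c("electrostatic", "edesolv", "npdesolv", "softcore")))
      stop("grids must be named electrostatic/edesolv/npdesolv/softcore")
    for (g in grids) {
      stopifnot(inherits(g, "potential_grid"))
      if (any(abs(g$center) > g$spacing / 2 + 1e-9))
        warning("grid is not centered on the solute's center of geometry")
    }
  }
  structure(list(atoms = atoms, effective_charges = effective_charges,
                 net_charge = as.double(net_charge),
                 stokes_radius = as.double(stokes_radius),
                 volume = as.double(volume), grids = grids),
            class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("<solute> %d atoms, z = %+.3f e, stokes radius %.2f A, grids: %s\n",
              n_atoms(x$atoms), x$net_charge, x$stokes_radius,
              if (length(x$grids)) paste(names(x$grids), collapse = ", ") else "none"))
  invisible(x)
}

# flat list passed to the C++ kernels
solute_cdata <- function(s) {
  list(atom_pos = s$atoms$positions, sasa = s$atoms$sasa,
       charge_pos = s$effective_charges$positions,
       charge_q = s$effective_charges$charges,
       grids = lapply(s$grids, function(g)
         list(values = g$values, origin = g$origin, spacing = g$spacing,
              cutoff_radius = g$cutoff_radius)),
       z = s$net_charge, a_dh = s$stokes_radius)
}

#' Continuum solvent model
#'
#' Stores temperature, relative permittivity and ionic composition, and
#' derives the inverse Debye length
#' `kappa^2 = e^2/(eps0 epsr kB T) * sum_i rho_i z_i^2` (number densities in
#' A^-3) together with the Bjerrum length.  For a monovalent salt at ionic
#' strength I the species list is `(I, +1), (I, -1)`.
#'
#' @param temperature K (default 300).
#' @param relative_permittivity dimensionless (default 78.5, liquid water).
#' @param ionic_strength convenience: molar ionic strength of a monovalent
#'   salt; expanded into two species.
#' @param species list of `c(concentration_mol_L, valence)` pairs; overrides
#'   `ionic_strength`.
#' @return an object of class `solvent_model` with elements `kappa` (1/A) and
#'   `bjerrum_length` (A).
#' @export
solvent_model <- function(temperature = 300, relative_permittivity = 78.5,
                          ionic_strength = NULL, species = NULL) {
  if (!(temperature > 0)) stop("temperature must be > 0")
  if (is.null(species)) {
    species <- if (is.null(ionic_strength) || ionic_strength == 0) list()
               else list(c(ionic_strength, 1), c(ionic_strength, -1))
  }
  kBT <- .kcal$kB * temperature
  lB <- .kcal$coulomb / (relative_permittivity * kBT)
  s2 <- 0
  for (sp in species) {
    if (sp[1] < 0) stop("ion concentrations must be >= 0")
    s2 <- s2 + .molar_to_A3(sp[1]) * sp[2]^2
  }
  kappa <- sqrt(4 * pi * lB * s2)
  structure(list(temperature = temperature,
                 relative_permittivity = relative_permittivity,
                 species = species, kappa = kappa, bjerrum_length = lB,
                 kBT = kBT),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("<solvent_model> T = %g K, eps_r = %g, kappa = %.5g 1/A (1/kappa = %s)\n",
              x$temperature, x$relative_permittivity, x$kappa,
              if (x$kappa > 0) sprintf("%.1f A", 1 / x$kappa) else "Inf"))
  invisible(x)
}

#' Inverse Debye length of a solvent model
#'
#' @param solvent a [solvent_model()].
#' @return kappa in 1/A (0 for pure water).
#' @export
inverse_debye_length <- function(solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  solvent$kappa
}

#' Cubic periodic (or open) simulation box
#'
#' @param side side length (A, > 0); cubic.
#' @param periodic apply periodic boundary conditions?
#' @return an object of class `box_spec`.
#' @export
box_spec <- function(side, periodic = TRUE) {
  if (!(side > 0)) stop("box side must be > 0")
  structure(list(side = as.double(side), periodic = isTRUE(periodic)),
            class = "box_spec")
}

#' Minimum-image wrap of a displacement vector
#'
#' Maps each component into the half-open interval `[-side/2, side/2)`.
#'
#' @param displacement numeric length-3 vector or n x 3 matrix (A).
#' @param box a [box_spec()].
#' @return wrapped displacement(s), same shape as the input.
#' @export
wrap_minimum_image <- function(displacement, box) {
  stopifnot(inherits(box, "box_spec"))
  if (!box$periodic) {
    warning("box is not periodic; returning displacement unchanged")
    return(displacement)
  }
  displacement - box$side * floor(displacement / box$side + 0.5)
}

# ---- quaternions (w, x, y, z), body -> lab ---------------------------------

#' Normalize quaternions to unit length
#' @param q length-4 vector or n x 4 matrix.
#' @return same shape, unit norm rows.
#' @export
quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

#' Quaternion product p * q
#' @param p,q length-4 quaternions (w, x, y, z).
#' @return the composed rotation `p` applied after `q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1]*q[1] - p[2]*q[2] - p[3]*q[3] - p[4]*q[4],
    p[1]*q[2] + p[2]*q[1] + p[3]*q[4] - p[4]*q[3],
    p[1]*q[3] - p[2]*q[4] + p[3]*q[1] + p[4]*q[2],
    p[1]*q[4] + p[2]*q[3] - p[3]*q[2] + p[4]*q[1])
}

#' Rotation matrix of a unit quaternion
#' @param q length-4 unit quaternion.
#' @return 3 x 3 rotation matrix mapping body-frame vectors to the lab frame.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion of a rotation vector
#' @param v length-3 rotation vector (axis * angle, rad).
#' @return length-4 unit quaternion.
#' @export
quat_from_rotvec <- function(v) {
  a <- sqrt(sum(v^2))
  if (a < 1e-12) return(c(1, v / 2))
  c(cos(a / 2), sin(a / 2) * v / a)
}

#' Uniform random unit quaternions
#' @param n how many.
#' @return n x 4 matrix of unit quaternions (uniform on SO(3)).
#' @export
quat_random <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  colnames(q) <- c("w", "x", "y", "z")
  q
}

#' Transform body-frame coordinates to the lab frame
#' @param coords n x 3 body-frame coordinates.
#' @param position length-3 lab-frame center (A).
#' @param quat length-4 unit quaternion.
#' @return n x 3 lab-frame coordinates.
#' @export
body_to_lab <- function(coords, position, quat) {
  sweep(coords %*% t(quat_to_matrix(quat)), 2, -as.double(position))
}

#' Transform lab-frame coordinates into a solute's body frame
#' @inheritParams body_to_lab
#' @return n x 3 body-frame coordinates.
#' @export
lab_to_body <- function(coords, position, quat) {
  sweep(coords, 2, as.double(position)) %*% quat_to_matrix(quat)
}
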