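# Pairwise energies and forces: Debye-Hueckel screened electrostatics, grid
# interpolation, the four gridded interaction terms, the per-pair grid/DH
# switch, and finite-difference forces and torques.

#' Debye-Hueckel pair description
#'
#' Two net charges treated as spheres with contact distance
#' `a = a_i + a_j`; by convention the sphere radii are the Stokes radii
#' unless overridden.
#'
#' @param z_i,z_j net charges (e).
#' @param a contact distance `a_i + a_j` (A, > 0).
#' @param solvent a [solvent_model()].
#' @return object of class `dh_pair`.
#' @export
dh_pair <- function(z_i, z_j, a, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  if (!(a > 0)) stop("contact distance a must be > 0")
  structure(list(z_i = z_i, z_j = z_j, a = a,
                 kappa = solvent$kappa,
                 epsr = solvent$relative_permittivity,
                 kBT = solvent$kBT),
            class = "dh_pair")
}

#' Screened-Coulomb potential of mean force
#'
#' `w(r) = z_i z_j e^2 exp(-kappa (r - a)) / (4 pi eps0 epsr r (1 + kappa a))`
#' at and beyond contact (r >= a) and `+Inf` (hard overlap) below contact.  In the unscreened
#' limit (`kappa = 0`) this is the bare Coulomb interaction
#' `kB T lambda_B z_i z_j / r`.
#'
#' @param r center-to-center distance(s) (A, > 0).
#' @param pair a [dh_pair()].
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
dh_pmf <- function(r, pair) {
  stopifnot(inherits(pair, "dh_pair"))
  if (any(r <= 0)) stop("r must be > 0")
  w <- .kcal$coulomb * pair$z_i * pair$z_j *
    exp(-pair$kappa * (r - pair$a)) / (pair$epsr * r * (1 + pair$kappa * pair$a))
  w[r < pair$a] <- Inf
  w
}

#' Analytic radial derivative of the Debye-Hueckel PMF
#' @inheritParams dh_pmf
#' @return dw/dr in kcal/mol/A (`NA` below contact).
#' @export
dh_pmf_deriv <- function(r, pair) {
  w <- dh_pmf(r, pair)
  d <- -w * (pair$kappa + 1 / r)
  d[!is.finite(w)] <- NA_real_
  d
}

#' Trilinear interpolation of a potential grid
#'
#' @param grid a [potential_grid()].
#' @param points length-3 vector or n x 3 matrix of body-frame coordinates (A).
#' @return interpolated value(s); points outside the grid box are an error
#'   (apply cutoff logic before interpolating).
#' @export
grid_value <- function(grid, points) {
  stopifnot(inherits(grid, "potential_grid"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  v <- cpp_grid_value(unclass(grid), points)
  if (anyNA(v)) stop("point(s) outside the grid bounding box")
  v
}

#' Charge-on-grid electrostatic energy with isotropic cutoff
#'
#' Sums `q_k * Phi(r_k)` over the charges whose distance from `grid_center`
#' is strictly below the grid's cutoff radius; charges at or beyond the
#' cutoff contribute exactly zero.
#'
#' @param grid an electrostatic [potential_grid()].
#' @param charges an [atom_set()] with positions already in the grid's frame.
#' @param grid_center center of the owning solute (same frame; default origin).
#' @return energy in kcal/mol.
#' @export
grid_charge_energy <- function(grid, charges, grid_center = c(0, 0, 0)) {
  stopifnot(inherits(grid, "potential_grid"), inherits(charges, "atom_set"))
  if (grid$kind != "electrostatic") stop("grid kind must be electrostatic")
  rel <- sweep(charges$positions, 2, as.double(grid_center))
  d <- sqrt(rowSums(rel^2))
  keep <- d < grid$cutoff_radius & charges$charges != 0
  if (!any(keep)) return(0)
  sum(charges$charges[keep] * grid_value(grid, charges$positions[keep, , drop = FALSE]))
}

#' Pairwise interaction free energy between two rigid solutes
#'
#' The interaction free energy is the sum of four gridded terms
#' (electrostatic charge-on-grid with the 1/2 double-counting factor,
#' electrostatic desolvation with squared charges, non-polar desolvation
#' weighted by SASA, and soft-core repulsion), with the electrostatic grid
#' term replaced by the analytic Debye-Hueckel net-charge tail whenever the
#' center-to-center distance reaches the switch radius (the smaller of the
#' two electrostatic grids' inscribed-sphere cutoffs).  Grid electrostatics
#' and the DH tail are never both applied to the same pair.
#'
#' @param s1,s2 [solute()]s.
#' @param pos1,pos2 lab-frame centers (A).
#' @param quat1,quat2 unit quaternions (default identity).
#' @param solvent a [solvent_model()].
#' @param box optional [box_spec()]; when periodic, the minimum-image
#'   displacement is used.
#' @param use_dh apply the Debye-Hueckel tail beyond the switch radius?
#' @param dh_cutoff distance beyond which the tail is dropped (A; default
#'   infinite).
#' @param terms character vector of terms to evaluate, subset of
#'   `c("electrostatic", "edesolv", "npdesolv", "softcore")`.  Default: every
#'   term for which both solutes carry the needed grid.  Requesting a term
#'   whose grid is missing is an error naming the term.
#' @param dh_radii optional length-2 override of the DH sphere radii
#'   (default: the Stokes radii).
#' @return object of class `pair_energy_breakdown` with components
#'   `electrostatic_grid`, `dh_tail`, `edesolv`, `npdesolv`, `softcore`,
#'   `total` (kcal/mol).
#' @export
pair_energy <- function(s1, s2, pos1 = c(0, 0, 0), pos2, quat1 = c(1, 0, 0, 0),
                        quat2 = c(1, 0, 0, 0), solvent, box = NULL,
                        use_dh = TRUE, dh_cutoff = Inf, terms = NULL,
                        dh_radii = NULL) {
  stopifnot(inherits(s1, "solute"), inherits(s2, "solute"),
            inherits(solvent, "solvent_model"))
  all_terms <- c("electrostatic", "edesolv", "npdesolv", "softcore")
  grid_of <- c(electrostatic = "electrostatic", edesolv = "edesolv",
               npdesolv = "npdesolv", softcore = "softcore")
  if (is.null(terms)) {
    terms <- all_terms[vapply(all_terms, function(tt)
      !is.null(s1$grids[[grid_of[tt]]]) && !is.null(s2$grids[[grid_of[tt]]]), TRUE)]
    if (use_dh) terms <- union(terms, "electrostatic")
  } else {
    terms <- match.arg(terms, all_terms, several.ok = TRUE)
    for (tt in setdiff(terms, "electrostatic")) {
      if (is.null(s1$grids[[grid_of[tt]]]) || is.null(s2$grids[[grid_of[tt]]]))
        stop(sprintf("term '%s' requested but a %s grid is missing", tt, grid_of[tt]))
    }
    if ("electrostatic" %in% terms && !use_dh &&
        (is.null(s1$grids$electrostatic) || is.null(s2$grids$electrostatic)))
      stop("term 'electrostatic' requested but an electrostatic grid is missing")
  }

  disp <- as.double(pos2) - as.double(pos1)
  if (!is.null(box) && box$periodic) disp <- wrap_minimum_image(disp, box)
  d <- sqrt(sum(disp^2))

  out <- list(electrostatic_grid = 0, dh_tail = 0, edesolv = 0,
              npdesolv = 0, softcore = 0)
  R1 <- quat_to_matrix(quat_normalize(quat1))
  R2 <- quat_to_matrix(quat_normalize(quat2))
  # lab offsets (relative to center 1) of the sources of solute 2 and v.v.
  to1 <- function(body2) sweep(body2 %*% t(R2), 2, -disp)   # frame centered on 1
  to2 <- function(body1) sweep(body1 %*% t(R1), 2, disp)    # frame centered on 2
  in_frame <- function(labrel, R) labrel %*% R              # lab -> body of owner

  if ("electrostatic" %in% terms) {
    g1 <- s1$grids$electrostatic; g2 <- s2$grids$electrostatic
    r_switch <- if (!is.null(g1) && !is.null(g2))
      min(g1$cutoff_radius, g2$cutoff_radius) else 0
    if (d < r_switch) {
      p2 <- to1(s2$effective_charges$positions)
      p1 <- to2(s1$effective_charges$positions)
      e1 <- grid_weighted_sum_rot(g1, p2, s2$effective_charges$charges, R1)
      e2 <- grid_weighted_sum_rot(g2, p1, s1$effective_charges$charges, R2)
      out$electrostatic_grid <- 0.5 * (e1 + e2)
    } else if (use_dh && d <= dh_cutoff &&
               s1$net_charge * s2$net_charge != 0) {
      if (is.null(dh_radii)) dh_radii <- c(s1$stokes_radius, s2$stokes_radius)
      pr <- dh_pair(s1$net_charge, s2$net_charge, sum(dh_radii), solvent)
      out$dh_tail <- dh_pmf(d, pr)
    }
  }
  if ("edesolv" %in% terms) {
    out$edesolv <-
      grid_weighted_sum_rot(s1$grids$edesolv, to1(s2$effective_charges$positions),
                            s2$effective_charges$charges^2, R1) +
      grid_weighted_sum_rot(s2$grids$edesolv, to2(s1$effective_charges$positions),
                            s1$effective_charges$charges^2, R2)
  }
  if ("npdesolv" %in% terms) {
    out$npdesolv <-
      grid_weighted_sum_rot(s1$grids$npdesolv, to1(s2$atoms$positions), s2$atoms$sasa, R1) +
      grid_weighted_sum_rot(s2$grids$npdesolv, to2(s1$atoms$positions), s1$atoms$sasa, R2)
  }
  if ("softcore" %in% terms) {
    out$softcore <-
      grid_weighted_sum_rot(s1$grids$softcore, to1(s2$atoms$positions),
                            rep(1, n_atoms(s2$atoms)), R1) +
      grid_weighted_sum_rot(s2$grids$softcore, to2(s1$atoms$positions),
                            rep(1, n_atoms(s1$atoms)), R2)
  }
  out$total <- out$electrostatic_grid + out$dh_tail + out$edesolv +
    out$npdesolv + out$softcore
  structure(out, class = "pair_energy_breakdown", distance = d)
}

# weighted gridded sum where `labrel` are source offsets from the grid
# owner's center in the LAB frame and R is the owner's rotation matrix
grid_weighted_sum_rot <- function(grid, labrel, weights, R) {
  if (is.null(grid)) return(0)
  dist <- sqrt(rowSums(labrel^2))
  keep <- dist < grid$cutoff_radius & weights != 0
  if (!any(keep)) return(0)
  body <- labrel[keep, , drop = FALSE] %*% R
  sum(weights[keep] * grid_value(grid, body))
}

#' @export
print.pair_energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<pair energy, d = %.2f A>  grid el %.4g | DH %.4g | ",
                     "edesolv %.4g | npdesolv %.4g | softcore %.4g | total %.4g kcal/mol\n"),
              attr(x, "distance"), x$electrostatic_grid, x$dh_tail, x$edesolv,
              x$npdesolv, x$softcore, x$total))
  invisible(x)
}

#' Finite-difference forces and torques for a solute pair
#'
#' Central differences of [pair_energy()] along the lab axes give the force
#' on solute 2 (the pair energy depends on positions only through the
#' relative displacement, so the force on solute 1 is equal and opposite);
#' central differences over small lab-frame rotations give the torque on
#' each solute about its center.
#'
#' @inheritParams pair_energy
#' @param delta translational finite-difference step (A, default 0.1).
#' @param dtheta rotational finite-difference step (rad, default 0.01).
#' @return list with `force1`, `force2` (kcal/mol/A) and `torque1`,
#'   `torque2` (kcal/mol).
#' @export
pair_forces_torques <- function(s1, s2, pos1 = c(0, 0, 0), pos2,
                                quat1 = c(1, 0, 0, 0), quat2 = c(1, 0, 0, 0),
                                solvent, box = NULL, use_dh = TRUE,
                                dh_cutoff = Inf, terms = NULL,
                                delta = 0.1, dtheta = 0.01) {
  if (!(delta > 0) || !(dtheta > 0)) stop("delta and dtheta must be > 0")
  E <- function(p2, q1, q2) pair_energy(s1, s2, pos1, p2, q1, q2, solvent,
                                        box = box, use_dh = use_dh,
                                        dh_cutoff = dh_cutoff, terms = terms)$total
  f2 <- numeric(3)
  for (k in 1:3) {
    dp <- dm <- as.double(pos2)
    dp[k] <- dp[k] + delta; dm[k] <- dm[k] - delta
    f2[k] <- -(E(dp, quat1, quat2) - E(dm, quat1, quat2)) / (2 * delta)
  }
  tq <- function(q, which) {
    t <- numeric(3)
    for (k in 1:3) {
      ax <- numeric(3); ax[k] <- dtheta
      qp <- quat_multiply(quat_from_rotvec(ax), q)
      qm <- quat_multiply(quat_from_rotvec(-ax), q)
      if (which == 1) {
        t[k] <- -(E(pos2, qp, quat2) - E(pos2, qm, quat2)) / (2 * dtheta)
      } else {
        t[k] <- -(E(pos2, quat1, qp) - E(pos2, quat1, qm)) / (2 * dtheta)
      }
    }
    t
  }
  list(force1 = -f2, force2 = f2,
       torque1 = tq(quat1, 1), torque2 = tq(quat2, 2))
}

#' Energy discontinuity at the grid/DH switch radius
#'
#' The per-pair switch from gridded electrostatics to the analytic tail can
#' leave a step in the energy (and hence a force impulse) at the switch
#' radius for non-centrosymmetric charge distributions; this diagnostic
#' reports its magnitude along a given direction.
#'
#' @inheritParams pair_energy
#' @param direction length-3 lab-frame direction (normalized internally).
#' @param eps probe offset from the switch radius (A).
#' @return list with the switch radius, the energies just inside and outside,
#'   and their difference (kcal/mol).
#' @export
switch_discontinuity <- function(s1, s2, solvent, direction = c(1, 0, 0),
                                 quat1 = c(1, 0, 0, 0), quat2 = c(1, 0, 0, 0),
                                 eps = 1e-3) {
  g1 <- s1$grids$electrostatic; g2 <- s2$grids$electrostatic
  if (is.null(g1) || is.null(g2)) stop("both solutes need electrostatic grids")
  rs <- min(g1$cutoff_radius, g2$cutoff_radius)
  u <- direction / sqrt(sum(direction^2))
  Ein <- pair_energy(s1, s2, c(0, 0, 0), u * (rs - eps), quat1, quat2,
                     solvent, use_dh = TRUE)$total
  Eout <- pair_energy(s1, s2, c(0, 0, 0), u * (rs + eps), quat1, quat2,
                      solvent, use_dh = TRUE)$total
  list(switch_radius = rs, inside = Ein, outside = Eout, jump = Eout - Ein)
}

#' Soft-core repulsion grid from an atom set
#'
#' Maps the inverse-power repulsion `sum_a eps (sigma_a / d_a)^n` onto a
#' node-centered cubic grid centered on the atoms' center of geometry,
#' truncated at `cap` so the potential (and its finite-difference forces)
#' stay smooth and finite at close contact.
#'
#' @param atoms an [atom_set()]; atomic radii are used as the per-atom sigma
#'   (atoms with radius 0 get `sigma0`).
#' @param side grid extent per axis (A).
#' @param spacing node spacing (A, default 1).
#' @param exponent inverse-power exponent n (default 6; production values
#'   should be >= 4 to keep contacts stiff).
#' @param epsilon energy prefactor (kcal/mol, default 1).
#' @param cap truncation value (kcal/mol, default 100).
#' @param sigma0 fallback sigma for zero-radius atoms (A, default 1).
#' @return a `softcore` [potential_grid()].
#' @export
softcore_from_atoms <- function(atoms, side, spacing = 1, exponent = 6,
                                epsilon = 1, cap = 100, sigma0 = 1) {
  stopifnot(inherits(atoms, "atom_set"))
  n <- grid_node_count(side, spacing)
  cog <- center_of_geometry(atoms)
  origin <- cog - (n - 1) / 2 * spacing
  sigma <- ifelse(atoms$radii > 0, atoms$radii, sigma0)
  vals <- cpp_inverse_power_grid(atoms$positions, sigma, epsilon, exponent,
                                 origin, spacing, rep(n, 3L), cap)
  dim(vals) <- rep(n, 3L)
  potential_grid(vals, origin, spacing, kind = "softcore")
}
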