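# Brownian dynamics propagation.  The full Ermak-McCammon propagator couples
# all solutes through the diffusion tensor; under the mean-field replacement
# D_ij -> D^short(phi_i) * I the tensor is position-independent within a step,
# its divergence term vanishes identically, and the update reduces to
#   r_i(t+dt) = r_i(t) + D_t^short(phi_i)/kBT * F_i * dt + R_i,
#   <R_i> = 0,  var(R_i) = 2 D_t^short(phi_i) dt  per component,
# with an analogous quaternion update for rotation.

#' Brownian dynamics run parameters
#'
#' @param dt integration timestep (ps, default 0.5).
#' @param n_steps number of steps.
#' @param record_every recording interval (ps; must be a multiple of `dt`;
#'   default 500 ps).
#' @param seed RNG seed for the run (integer or NULL to keep the current RNG
#'   state).
#' @param use_dh apply the long-range Debye-Hueckel tail?
#' @param dh_cutoff DH pair cutoff (A); `NULL` = 4x the largest electrostatic
#'   grid side, rescaled to half the box when larger.
#' @param R_cut local-volume radius (A); `NULL` = 4x the largest grid side
#'   capped at half the box.
#' @param use_hydro apply the mean-field hydrodynamic slowdown (Tokuyama /
#'   Cichocki short-time coefficients)?
#' @param include_self_phi count a solute's own volume in its local volume
#'   fraction?
#' @param phi_stride steps between local volume fraction updates (default 1).
#' @param viscosity solvent viscosity (cP, default 0.89; water at 300 K) for
#'   Stokes-Einstein infinite-dilution coefficients.
#' @param delta,dtheta finite-difference steps for forces (A) and torques (rad).
#' @param equilibration_fraction fraction of the run treated as equilibration
#'   by analysis defaults (default 0.2).
#' @return an object of class `bd_params`.
#' @export
bd_params <- function(dt = 0.5, n_steps, record_every = 500, seed = NULL,
                      use_dh = TRUE, dh_cutoff = NULL, R_cut = NULL,
                      use_hydro = TRUE, include_self_phi = FALSE,
                      phi_stride = 1L, viscosity = 0.89,
                      delta = 0.1, dtheta = 0.01,
                      equilibration_fraction = 0.2) {
  if (!(dt > 0)) stop("dt must be > 0")
  if (record_every < dt) stop("record_every must be >= dt")
  stride <- round(record_every / dt)
  if (abs(stride * dt - record_every) > 1e-9)
    stop("record_every must be a multiple of dt")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 record_stride = as.integer(stride), seed = seed,
                 use_dh = use_dh, dh_cutoff = dh_cutoff, R_cut = R_cut,
                 use_hydro = use_hydro, include_self_phi = include_self_phi,
                 phi_stride = as.integer(phi_stride), viscosity = viscosity,
                 delta = delta, dtheta = dtheta,
                 equilibration_fraction = equilibration_fraction),
            class = "bd_params")
}

#' Stokes-Einstein infinite-dilution diffusion coefficients
#'
#' @param stokes_radius hydrodynamic radius (A).
#' @param temperature K.
#' @param viscosity cP.
#' @return list with `Dt` (A^2/ps) and `Dr` (1/ps).
#' @export
stokes_einstein_d0 <- function(stokes_radius, temperature = 300, viscosity = 0.89) {
  kB <- 1.380649e-23                      # J/K
  eta <- viscosity * 1e-3                 # Pa s
  sig <- stokes_radius * 1e-10            # m
  Dt <- kB * temperature / (6 * pi * eta * sig) * 1e8      # m^2/s -> A^2/ps
  Dr <- kB * temperature / (8 * pi * eta * sig^3) * 1e-12  # 1/s -> 1/ps
  list(Dt = Dt, Dr = Dr)
}

#' Gaussian random displacement of free Brownian motion
#'
#' Three independent normal deviates with zero mean and per-component
#' variance `2 D dt`.
#'
#' @param D translational diffusion coefficient (A^2/ps, >= 0).
#' @param dt timestep (ps).
#' @return length-3 displacement (A).
#' @export
random_displacement <- function(D, dt) {
  if (D < 0) stop("D must be >= 0")
  rnorm(3, 0, sqrt(2 * D * dt))
}

#' Single mean-field BD translation step
#'
#' @param position length-3 current center (A).
#' @param force length-3 force (kcal/mol/A; must be finite).
#' @param D short-time translational diffusion coefficient (A^2/ps).
#' @param dt timestep (ps).
#' @param kBT thermal energy (kcal/mol).
#' @param noise include the stochastic term? (`FALSE` gives the pure drift,
#'   a deterministic test hook.)
#' @return new position (A).
#' @export
bd_translation_step <- function(position, force, D, dt, kBT, noise = TRUE) {
  if (!all(is.finite(force))) stop("non-finite force")
  position + D / kBT * force * dt + if (noise) random_displacement(D, dt) else 0
}

#' Single mean-field BD rotation step
#'
#' Drift `D_r/kBT * torque * dt` about the torque axis plus an isotropic
#' Gaussian random rotation with per-axis variance `2 D_r dt`, applied as a
#' lab-frame quaternion increment and renormalized.
#'
#' @param quat length-4 unit quaternion.
#' @param torque length-3 torque (kcal/mol; finite).
#' @param Dr short-time rotational diffusion coefficient (1/ps).
#' @inheritParams bd_translation_step
#' @return new unit quaternion.
#' @export
bd_rotation_step <- function(quat, torque, Dr, dt, kBT, noise = TRUE) {
  if (!all(is.finite(torque))) stop("non-finite torque")
  rv <- Dr / kBT * torque * dt +
    if (noise) rnorm(3, 0, sqrt(2 * Dr * dt)) else 0
  quat_normalize(quat_multiply(quat_from_rotvec(rv), quat))
}

#' Random non-overlapping initial placement
#'
#' @param n number of solutes.
#' @param box a [box_spec()]; positions are drawn in `[-side/2, side/2)^3`.
#' @param radii contact radii (A; scalar or length n).
#' @param max_try placement attempts per solute before giving up.
#' @return n x 3 matrix of centers.
#' @export
place_random <- function(n, box, radii, max_try = 10000) {
  if (length(radii) == 1) radii <- rep(radii, n)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_try)) {
      p <- runif(3, -box$side / 2, box$side / 2)
      ok <- TRUE
      if (i > 1) for (j in seq_len(i - 1)) {
        d <- wrap_minimum_image(p - pos[j, ], box)
        if (sqrt(sum(d^2)) < radii[i] + radii[j]) { ok <- FALSE; break }
      }
      if (ok) { pos[i, ] <- p; break }
    }
    if (!ok) stop("could not place solutes without overlap; increase the box size")
  }
  pos
}

#' Rigid-body Brownian dynamics of a solute suspension
#'
#' Propagates `n_copies` of each solute species in a periodic cubic box with
#' pairwise forces from [pair_energy()] finite differences, the
#' Debye-Hueckel tail beyond the grid switch radius, and the mean-field
#' hydrodynamic slowdown.  Positions/orientations and per-term energies are
#' recorded every `record_every` ps.
#'
#' @param solutes a [solute()] or list of them (species).
#' @param n_copies copies per species (recycled).
#' @param box a [box_spec()].
#' @param solvent a [solvent_model()].
#' @param params a [bd_params()].
#' @param positions optional n x 3 initial centers (A); default random
#'   non-overlapping placement.
#' @param quaternions optional n x 4 initial orientations; default uniform
#'   random.
#' @return an object of class `bd_trajectory`: recorded `times` (ps),
#'   `positions` (n x 3 x frames, wrapped), `images` (periodic image
#'   counts), `quaternions`, per-frame per-term `energies`, local volume
#'   fractions `phi`, plus run metadata.
#' @export
simulate_bd <- function(solutes, n_copies = 1, box, solvent, params,
                        positions = NULL, quaternions = NULL) {
  if (inherits(solutes, "solute")) solutes <- list(solutes)
  stopifnot(inherits(box, "box_spec"), inherits(solvent, "solvent_model"),
            inherits(params, "bd_params"))
  nsp <- length(solutes)
  n_copies <- rep_len(n_copies, nsp)
  sp_idx <- rep(seq_len(nsp), n_copies)
  N <- length(sp_idx)
  if (!is.null(params$seed)) set.seed(params$seed)

  radii <- vapply(solutes, `[[`, numeric(1), "stokes_radius")[sp_idx]
  vols <- vapply(solutes, `[[`, numeric(1), "volume")[sp_idx]
  if (is.null(positions)) positions <- place_random(N, box, radii)
  if (is.null(quaternions)) quaternions <- quat_random(N)
  positions <- matrix(as.double(positions), N, 3)
  quaternions <- matrix(as.double(quaternions), N, 4)

  el_sides <- vapply(solutes, function(s)
    if (is.null(s$grids$electrostatic)) 0
    else max((s$grids$electrostatic$shape - 1) * s$grids$electrostatic$spacing),
    numeric(1))
  dh_cut <- params$dh_cutoff
  if (is.null(dh_cut)) {
    dh_cut <- 4 * max(el_sides)
    if (dh_cut <= 0 || dh_cut > box$side / 2) dh_cut <- box$side / 2
  }
  R_cut <- params$R_cut
  if (is.null(R_cut)) R_cut <- local_volume_cutoff(solutes, box)

  d0 <- lapply(radii, stokes_einstein_d0, temperature = solvent$temperature,
               viscosity = params$viscosity)
  D0t <- vapply(d0, `[[`, numeric(1), "Dt")
  D0r <- vapply(d0, `[[`, numeric(1), "Dr")

  raw <- cpp_simulate(lapply(solutes, solute_cdata), as.integer(sp_idx),
                      positions, quaternions,
                      box$side, box$periodic,
                      solvent$kappa, solvent$relative_permittivity, solvent$kBT,
                      params$dt, params$n_steps, params$record_stride,
                      params$use_dh, dh_cut,
                      params$use_hydro, R_cut, params$include_self_phi,
                      params$phi_stride, D0t, D0r, radii, vols,
                      params$delta, params$dtheta)

  energies <- as.data.frame(raw$energies)
  names(energies) <- c("electrostatic_grid", "dh_tail", "edesolv",
                       "npdesolv", "softcore", "total")
  energies <- cbind(time = raw$times, energies)

  structure(list(times = raw$times, positions = raw$positions,
                 images = raw$images, quaternions = raw$quaternions,
                 energies = energies, phi = raw$phi,
                 box = box, solvent = solvent, params = params,
                 species = sp_idx, solutes = solutes,
                 D0t = D0t, D0r = D0r, dh_cutoff = dh_cut, R_cut = R_cut),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<bd_trajectory> %d solutes, %d frames over %.4g ps ",
                     "(dt = %g ps), box %.4g A %s\n"),
              dim(x$positions)[1], length(x$times), max(x$times),
              x$params$dt, x$box$side,
              if (x$box$periodic) "periodic" else "open"))
  cat(sprintf("  mean total energy %.4g kcal/mol, DH cutoff %.4g A, R_cut %.4g A\n",
              mean(x$energies$total), x$dh_cutoff, x$R_cut))
  invisible(x)
}

#' Number of solutes / frames in a trajectory
#' @param traj a `bd_trajectory`.
#' @return integer.
#' @export
n_solutes <- function(traj) dim(traj$positions)[1]

#' @rdname n_solutes
#' @export
n_frames <- function(traj) length(traj$times)

#' Unwrapped (image-corrected) positions
#'
#' @param traj a `bd_trajectory`.
#' @return n x 3 x frames array of continuous trajectories (A).
#' @export
unwrap_positions <- function(traj) {
  traj$positions + traj$images * traj$box$side
}

#' Equilibration detection
#'
#' Flags the earliest recorded time after which both the radial distribution
#' function (segment-wise comparison, see [gr_convergence()]) and the
#' running mean energy are stable.  Energy stability: each block mean stays
#' within `energy_k` standard errors (estimated from the within-block
#' scatter, which is insensitive to slow drifts) of the mean over the final
#' quarter of the run.
#'
#' @param traj a `bd_trajectory`.
#' @param n_segments number of blocks (default 20).
#' @param energy_k allowed deviation in within-block standard errors
#'   (default 4).
#' @param gr_threshold maximum allowed g(r) segment deviation (passed to
#'   [gr_convergence()]).
#' @return list with `equilibrated_from` (ps, `NA` when never stable),
#'   per-block energy means, and the g(r) convergence report.
#' @export
detect_equilibration <- function(traj, n_segments = 20, energy_k = 4,
                                 gr_threshold = 0.15) {
  e <- traj$energies$total
  nf <- length(e)
  if (nf < 2 * n_segments) stop("too few frames for equilibration analysis")
  blocks <- split(seq_len(nf), cut(seq_len(nf), n_segments, labels = FALSE))
  bm <- vapply(blocks, function(ix) mean(e[ix]), numeric(1))
  bl <- vapply(blocks, length, numeric(1))
  # noise scale from within-block scatter (robust against drift)
  se <- stats::median(vapply(blocks, function(ix) sd(e[ix]), numeric(1))) /
    sqrt(stats::median(bl))
  last_q <- max(1, ceiling(3 / 4 * n_segments)):n_segments
  mu <- mean(bm[last_q])
  tol <- energy_k * max(se, 1e-12 * max(1, abs(mu)))
  stable <- abs(bm - mu) <= tol
  first <- NA_real_
  for (b in seq_len(n_segments)) {
    if (all(stable[b:n_segments])) {
      first <- traj$times[blocks[[b]][1]]
      break
    }
  }
  gr <- if (n_solutes(traj) >= 2)
    gr_convergence(traj, n_segments = n_segments, threshold = gr_threshold)
  else NULL
  if (!is.null(gr) && !gr$converged) first <- NA_real_
  list(equilibrated_from = first, block_means = bm, gr = gr)
}
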