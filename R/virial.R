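# Second osmotic virial coefficients for the two-sphere test systems:
# the closed-form long-range expression (second-order expansion of the Mayer
# function with the screened-Coulomb PMF), 1-D adaptive quadrature, and the
# 3-D lattice-integration protocol over a periodic-box-sized cube.

#' B22 result container
#'
#' @param value B22 (A^3).
#' @param method one of `"analytic"`, `"quadrature"`, `"lattice"`.
#' @param lb lower integration bound (A).
#' @param subset_mean,subset_sd random-subset statistics (lattice only).
#' @param n number of lattice vertices / quadrature evaluations used.
#' @param expansion_valid `FALSE` when |w(lb)|/kBT is too large for the
#'   second-order expansion.
#' @return object of class `b22_result`.
#' @export
b22_result <- function(value, method, lb, subset_mean = NA_real_,
                       subset_sd = NA_real_, n = NA_integer_,
                       expansion_valid = TRUE) {
  structure(list(value = value, method = method, lb = lb,
                 subset_mean = subset_mean, subset_sd = subset_sd,
                 n = n, expansion_valid = expansion_valid),
            class = "b22_result")
}

#' @export
print.b22_result <- function(x, ...) {
  cat(sprintf("<B22 %s> %.6g A^3 (lb = %.2f A%s)\n", x$method, x$value, x$lb,
              if (!is.na(x$subset_mean))
                sprintf("; subsets: %.6g +- %.3g", x$subset_mean, x$subset_sd)
              else ""))
  if (!x$expansion_valid)
    cat("  warning: |w(lb)|/kBT is large; the second-order expansion is unreliable\n")
  invisible(x)
}

#' Uniformly charged fullerene-like sphere pair
#'
#' Two rigid shells of `n_atoms` point charges placed quasi-uniformly
#' (Fibonacci spiral) on a sphere of the given radius, each carrying
#' `z/n_atoms` e, with an analytically gridded screened-Coulomb potential
#' ([sphere_dh_grid()]) and an optional soft-core grid attached.
#'
#' @param z1,z2 net charges (e).
#' @param solvent a [solvent_model()].
#' @param radius shell radius (A, default 6).
#' @param n_atoms charges per sphere (default 180).
#' @param grid_side electrostatic grid extent (A, default 100); 0 skips the
#'   grid (pure Debye-Hueckel solutes).
#' @param grid_spacing grid spacing (A, default 1).
#' @param softcore_side soft-core grid extent (A, default 26); 0 skips it.
#' @param atom_radius per-atom soft-core sigma (A, default 1.2).
#' @return list of two [solute()]s with class `sphere_system`.
#' @export
make_sphere_system <- function(z1, z2, solvent, radius = 6, n_atoms = 180,
                               grid_side = 100, grid_spacing = 1,
                               softcore_side = 26, atom_radius = 1.2) {
  one <- function(z) {
    pts <- fibonacci_sphere(n_atoms, radius)
    atoms <- atom_set(pts, charges = rep(z / n_atoms, n_atoms),
                      radii = rep(atom_radius, n_atoms))
    grids <- list()
    if (grid_side > 0)
      grids$electrostatic <- sphere_dh_grid(z, radius, solvent,
                                            side = grid_side,
                                            spacing = grid_spacing)
    if (softcore_side > 0)
      grids$softcore <- softcore_from_atoms(atoms, side = softcore_side,
                                            spacing = grid_spacing)
    solute(atoms, stokes_radius = radius, net_charge = z, grids = grids)
  }
  structure(list(s1 = one(z1), s2 = one(z2),
                 contact = 2 * radius, radius = radius),
            class = "sphere_system")
}

# quasi-uniform points on a sphere (golden-angle spiral), recentered so the
# center of geometry sits exactly at the origin with all points on the shell
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  for (it in 1:100) {
    cog <- colMeans(pts)
    if (max(abs(cog)) < 1e-12) break
    pts <- sweep(pts, 2, cog)
    pts <- pts / sqrt(rowSums(pts^2))
  }
  radius * pts
}

#' Analytic screened-Coulomb sphere potential on a grid
#'
#' The exterior potential of a uniformly charged sphere in Debye-Hueckel
#' electrolyte,
#' `Phi(r) = z e exp(-kappa (r - a0)) / (4 pi eps0 epsr r (1 + kappa a0))`
#' (kcal/mol/e), mapped onto a node-centered cubic grid; the interior
#' (r below a0) is filled with the contact value.  Stands in for a linearized
#' Poisson-Boltzmann solution, which it equals outside the sphere.
#'
#' @param z net charge (e).
#' @param a0 sphere radius (A).
#' @param solvent a [solvent_model()].
#' @param side grid extent (A, >= 4 a0).
#' @param spacing node spacing (A, default 1).
#' @return an electrostatic [potential_grid()].
#' @export
sphere_dh_grid <- function(z, a0, solvent, side, spacing = 1) {
  stopifnot(inherits(solvent, "solvent_model"))
  if (side < 4 * a0) stop("grid side must be at least 4 * a0")
  n <- grid_node_count(side, spacing)
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  r <- sqrt(r2)
  r[r < a0] <- a0
  kap <- solvent$kappa
  vals <- .kcal$coulomb * z * exp(-kap * (r - a0)) /
    (solvent$relative_permittivity * r * (1 + kap * a0))
  origin <- rep(ax[1], 3)
  potential_grid(vals, origin, spacing, kind = "electrostatic")
}

#' Closed-form long-range B22 for a Debye-Hueckel pair
#'
#' Expanding the Mayer function `exp(-w/kBT) - 1` to second order in
#' `w/kBT` and integrating `-1/2 (exp(-w/kBT) - 1) 4 pi r^2` from `lb` to
#' infinity with the screened-Coulomb PMF gives, for kappa > 0,
#' ```
#' B22(lb) = 2 pi beta C exp(-kappa(lb-a)) (lb/kappa + 1/kappa^2) / (1+kappa a)
#'         -   pi (beta C)^2 exp(-2 kappa(lb-a)) / (2 kappa (1+kappa a)^2)
#' ```
#' with `C = z_i z_j e^2/(4 pi eps0 epsr)` and `beta = 1/kBT`.  At the
#' canonical lower bound `lb = a + 1/kappa` the exponentials reduce to
#' `1/e` and `1/e^2` and the first term carries the familiar
#' `(2 + kappa a)/(1 + kappa a)` factor.
#'
#' @param pair a [dh_pair()].
#' @param lb lower integration bound (A); default `a + 1/kappa`.
#' @param warn_threshold `|w(lb)|/kBT` above which the expansion is flagged
#'   (default 0.5).
#' @return a [b22_result()] in A^3.
#' @export
b22_analytic_longrange <- function(pair, lb = NULL,
                                   warn_threshold = 0.5) {
  stopifnot(inherits(pair, "dh_pair"))
  kap <- pair$kappa
  if (kap <= 0) stop("the long-range closed form needs kappa > 0 (screened potential)")
  if (is.null(lb)) lb <- pair$a + 1 / kap
  if (pair$z_i == 0 || pair$z_j == 0)
    return(b22_result(0, "analytic", lb))
  C <- .kcal$coulomb * pair$z_i * pair$z_j / pair$epsr
  beta <- 1 / pair$kBT
  wlb <- abs(dh_pmf(lb, pair)) * beta
  valid <- wlb < warn_threshold
  if (!valid)
    warning(sprintf("|w(lb)|/kBT = %.2f; second-order expansion unreliable", wlb))
  e1 <- exp(-kap * (lb - pair$a))
  t1 <- 2 * pi * beta * C * e1 * (lb / kap + 1 / kap^2) / (1 + kap * pair$a)
  t2 <- -pi * (beta * C)^2 * e1^2 / (2 * kap * (1 + kap * pair$a)^2)
  b22_result(t1 + t2, "analytic", lb, expansion_valid = valid)
}

#' B22 by adaptive quadrature of an isotropic PMF
#'
#' Numerically integrates `-1/2 (exp(-w/kBT) - 1) 4 pi r^2` (order
#' `"full"`) or its second-order expansion (order `"second"`) from `lb` to
#' infinity.
#'
#' @param w function of distance r (A) returning kcal/mol; may return `Inf`
#'   (hard core).
#' @param lb lower bound (A).
#' @param kBT thermal energy (kcal/mol).
#' @param order `"full"` or `"second"`.
#' @param breaks optional interior breakpoints (A) at which `w` is
#'   discontinuous (e.g. a hard-sphere diameter).
#' @param upper upper bound (default `Inf`).
#' @param rel.tol quadrature tolerance.
#' @return a [b22_result()] in A^3.
#' @export
b22_quadrature <- function(w, lb, kBT, order = c("full", "second"),
                           breaks = NULL, upper = Inf, rel.tol = 1e-9) {
  order <- match.arg(order)
  beta <- 1 / kBT
  integrand <- function(r) {
    x <- beta * vapply(r, w, numeric(1))
    f <- if (order == "full") exp(-x) - 1 else -x + x^2 / 2
    f[is.infinite(x) & x > 0] <- -1
    -0.5 * f * 4 * pi * r^2
  }
  pts <- sort(unique(c(lb, breaks[breaks > lb & breaks < upper], upper)))
  tot <- 0; neval <- 0L
  for (i in seq_len(length(pts) - 1)) {
    quad <- tryCatch(
      integrate(integrand, pts[i], pts[i + 1], rel.tol = rel.tol,
                subdivisions = 500L),
      error = function(e) stop("B22 quadrature did not converge: ",
                               conditionMessage(e)))
    tot <- tot + quad$value
    neval <- neval + quad$subdivisions
  }
  b22_result(tot, "quadrature", lb, n = neval)
}

#' Lattice-integrated long-range B22 for a two-sphere system
#'
#' One particle is fixed at the center of a cubic box; the second visits
#' every vertex of a regular lattice (avoiding overlaps with the central
#' particle) and the pair interaction energy is evaluated at each vertex via
#' the gridded electrostatic term with its isotropic cutoff, the
#' Debye-Hueckel net-charge tail beyond the grid switch radius (when
#' enabled) and the soft-core term.  The virial coefficient is the Riemann
#' sum `-1/2 sum_{r_k >= lb} (exp(-E_k/kBT) - 1) dV` with `dV` the
#' per-vertex volume.  Subset statistics follow the random-resampling
#' protocol: `subsets[1]` random draws of `subsets[2]` vertices each,
#' every draw rescaled to the full integration volume (unbiased estimator).
#'
#' @param system a [make_sphere_system()] result (or list of two solutes
#'   plus `contact`).
#' @param solvent a [solvent_model()].
#' @param lb lower bound (A; must be at or beyond contact).
#' @param box_side lattice box side (A, default 400).
#' @param lattice_n vertices per axis (default 100).
#' @param use_dh include the Debye-Hueckel tail?
#' @param dh_cutoff DH distance cutoff (A; default `Inf`: within the lattice
#'   box the tail is never dropped).
#' @param subsets `c(n_subsets, subset_size)` (default `c(100, 1e5)`); NULL
#'   skips subset statistics.
#' @param seed RNG seed for the subset draws.
#' @return a [b22_result()] in A^3 with subset mean/SD.
#' @export
b22_lattice <- function(system, solvent, lb, box_side = 400, lattice_n = 100,
                        use_dh = TRUE, dh_cutoff = Inf,
                        subsets = c(100, 1e5), seed = NULL) {
  stopifnot(inherits(solvent, "solvent_model"))
  contact <- system$contact
  if (lb < contact) stop("lb lies inside the overlap (contact) region")
  spacing <- box_side / lattice_n
  ticks <- (seq_len(lattice_n) - (lattice_n + 1) / 2) * spacing
  offsets <- as.matrix(expand.grid(x = ticks, y = ticks, z = ticks))
  d <- sqrt(rowSums(offsets^2))
  keep <- d >= contact                      # avoid overlaps
  offsets <- offsets[keep, , drop = FALSE]
  d <- d[keep]
  E <- cpp_lattice_energies(solute_cdata(system$s1), solute_cdata(system$s2),
                            offsets, solvent$kappa,
                            solvent$relative_permittivity, use_dh, dh_cutoff)
  dV <- spacing^3
  f <- exp(-E / solvent$kBT) - 1
  counted <- d >= lb
  value <- -0.5 * sum(f[counted]) * dV + 0   # + 0 normalizes a signed zero
  sm <- ssd <- NA_real_
  if (!is.null(subsets)) {
    if (!is.null(seed)) set.seed(seed)
    M <- length(f)
    m <- min(as.integer(subsets[2]), M)
    vals <- vapply(seq_len(subsets[1]), function(i) {
      ix <- sample.int(M, m)
      -0.5 * (M / m) * sum(f[ix][d[ix] >= lb]) * dV
    }, numeric(1))
    sm <- mean(vals); ssd <- sd(vals)
  }
  b22_result(value, "lattice", lb, subset_mean = sm, subset_sd = ssd,
             n = length(f))
}
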