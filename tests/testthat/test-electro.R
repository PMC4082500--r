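test_that("dh_pmf is +Inf below contact and matches an SI-constant oracle", {
  pair <- dh_pair(1, 1, 12, solv5)
  expect_identical(dh_pmf(6, pair), Inf)        # r = a/2
  expect_error(dh_pmf(0, pair), "> 0")
  # independent evaluation constant-by-constant in SI, converted to kcal/mol
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  NA_ <- 6.02214076e23
  kap_SI <- sqrt(e^2 / (eps0 * 78.5 * kB * 300) * 2 * 0.005 * 1000 * NA_)  # 1/m
  r <- 55e-10; a <- 12e-10
  w_SI <- e^2 * exp(-kap_SI * (r - a)) / (4 * pi * eps0 * 78.5 * r * (1 + kap_SI * a))
  w_kcal <- w_SI * NA_ / 4184
  expect_equal(dh_pmf(55, pair), w_kcal, tolerance = 1e-9)
})

test_that("dh_pmf reduces to the bare Coulomb form when kappa = 0", {
  water <- solvent_model(300, 78.5)
  pair <- dh_pair(1, 1, 2, water)
  r <- c(5, 20, 80)
  expect_equal(dh_pmf(r, pair), water$kBT * water$bjerrum_length / r,
               tolerance = 1e-12)
})

test_that("dh_pmf is monotone and has the sign of z_i z_j", {
  r <- seq(12, 200, by = 0.5)
  rep_ <- dh_pmf(r, dh_pair(3, 2, 12, solv5))
  att <- dh_pmf(r, dh_pair(3, -2, 12, solv5))
  expect_true(all(rep_ > 0) && all(diff(rep_) < 0))
  expect_true(all(att < 0) && all(diff(att) > 0))
})

test_that("doubling kappa rescales the PMF by the predicted factor", {
  I <- 0.01
  s1 <- solvent_model(300, 78.5, ionic_strength = I)
  s4 <- solvent_model(300, 78.5, ionic_strength = 4 * I)  # kappa doubles
  k <- s1$kappa; a <- 12
  expect_equal(s4$kappa, 2 * k, tolerance = 1e-12)
  for (r in c(20, 43, 90)) {
    ratio <- dh_pmf(r, dh_pair(2, 2, a, s4)) / dh_pmf(r, dh_pair(2, 2, a, s1))
    predicted <- exp(-k * (r - a)) * (1 + k * a) / (1 + 2 * k * a)
    expect_equal(ratio, predicted, tolerance = 1e-12)
  }
})

test_that("trilinear interpolation is exact on nodes and at cell centers", {
  g <- ramp_grid(n = 4, spacing = 1.5,
                 f = function(x, y, z) sin(x) + cos(y) * z)
  # node identity
  for (ijk in list(c(1, 1, 1), c(2, 3, 4), c(4, 4, 4))) {
    p <- g$origin + (ijk - 1) * g$spacing
    expect_equal(grid_value(g, p), g$values[ijk[1], ijk[2], ijk[3]])
  }
  # cell center = mean of the 8 corners
  corners <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  p <- g$origin + (c(1, 1, 1) - 1 + 0.5) * g$spacing
  expect_equal(grid_value(g, p),
               mean(apply(corners, 1, function(c_) g$values[c_[1], c_[2], c_[3]])))
})

test_that("trilinear interpolation equals the 8-term expansion oracle", {
  g <- ramp_grid(n = 6, spacing = 0.8,
                 f = function(x, y, z) x^2 - y * z + 0.3 * z)
  tri_oracle <- function(g, p) {
    t <- (p - g$origin) / g$spacing
    i <- pmin(floor(t), g$shape - 2); f <- t - i
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
             (if (dz) f[3] else 1 - f[3])
      s <- s + wgt * g$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
    }
    s
  }
  set.seed(33)
  lim <- max(abs(g$origin))
  pts <- matrix(runif(60, -lim, lim), 20, 3)
  expect_equal(grid_value(g, pts),
               apply(pts, 1, function(p) tri_oracle(g, p)), tolerance = 1e-12)
  expect_error(grid_value(g, c(100, 0, 0)), "outside")
})

test_that("charge-on-grid energy applies the isotropic cutoff exactly", {
  g <- ramp_grid(n = 9, spacing = 1)   # cutoff = 4 A
  # all charges beyond the cutoff contribute 0
  far <- atom_set(matrix(c(4, 0, 0, 0, 5, 0), 2, 3, byrow = TRUE), charges = 1)
  expect_equal(grid_charge_energy(g, far), 0)
  # single unit charge on a node inside the cutoff picks up the node value
  on_node <- atom_set(matrix(c(1, 0, 0), 1, 3), charges = 1)
  expect_equal(grid_charge_energy(g, on_node), grid_value(g, c(1, 0, 0)))
  # mixed set equals a per-charge masked brute-force sum
  set.seed(4)
  pos <- matrix(runif(45, -5, 5), 15, 3)
  q <- rnorm(15)
  mixed <- atom_set(pos, charges = q)
  oracle <- 0
  for (i in 1:15) {
    if (sqrt(sum(pos[i, ]^2)) < g$cutoff_radius)
      oracle <- oracle + q[i] * grid_value(g, pos[i, ])
  }
  expect_equal(grid_charge_energy(g, mixed), oracle, tolerance = 1e-12)
})

test_that("neutral solutes with no grids have identically zero pair energy", {
  s <- bare_sphere(6, 0)
  pe <- pair_energy(s, s, pos2 = c(20, 0, 0), solvent = solv5)
  expect_equal(pe$total, 0)
  expect_equal(pe$electrostatic_grid, 0)
  expect_equal(pe$dh_tail, 0)
})

test_that("the pair energy is symmetric under exchanging the solutes", {
  sys <- make_sphere_system(3, -2, solv5, grid_side = 40, softcore_side = 16)
  set.seed(5)
  for (i in 1:4) {
    d <- runif(3, -1, 1) * 12 + c(16, 0, 0)
    q1 <- quat_normalize(rnorm(4)); q2 <- quat_normalize(rnorm(4))
    e12 <- pair_energy(sys$s1, sys$s2, pos2 = d, quat1 = q1, quat2 = q2,
                       solvent = solv5)$total
    e21 <- pair_energy(sys$s2, sys$s1, pos2 = -d, quat1 = q2, quat2 = q1,
                       solvent = solv5)$total
    expect_equal(e12, e21, tolerance = 1e-9)
  }
})

test_that("beyond the switch radius the pair energy is the analytic DH tail", {
  sys <- make_sphere_system(2, 2, solv5, grid_side = 40, softcore_side = 0)
  pair <- dh_pair(2, 2, 12, solv5)
  for (d in c(21, 35, 80)) {
    pe <- pair_energy(sys$s1, sys$s2, pos2 = c(0, d, 0), solvent = solv5)
    expect_equal(pe$electrostatic_grid, 0)
    expect_equal(pe$dh_tail, dh_pmf(d, pair), tolerance = 1e-12)
    expect_equal(pe$total, pe$dh_tail)
  }
  # the tail is dropped beyond dh_cutoff
  pe <- pair_energy(sys$s1, sys$s2, pos2 = c(0, 50, 0), solvent = solv5,
                    dh_cutoff = 40)
  expect_equal(pe$total, 0)
})

test_that("gridded electrostatics matches the DH PMF where the shell is inside the cutoff", {
  # centrosymmetric two-sphere case: for separations where the partner's full
  # charge shell lies inside the isotropic cutoff, the charge-on-grid energy
  # reproduces the analytic screened-Coulomb PMF closely (the grid/DH contact
  # conventions, a0 = 6 vs a = 12, nearly cancel)
  sys <- make_sphere_system(2, 2, solv5, grid_side = 60, softcore_side = 0)
  pair <- dh_pair(2, 2, 12, solv5)
  cutoff <- sys$s1$grids$electrostatic$cutoff_radius
  for (d in c(16, 20, 23.9)) {
    stopifnot(d <= cutoff - 6)
    pe <- pair_energy(sys$s1, sys$s2, pos2 = c(d, 0, 0), solvent = solv5)
    expect_equal(pe$electrostatic_grid, dh_pmf(d, pair), tolerance = 0.025)
  }
})

test_that("the switch diagnostic reports the acknowledged boundary discontinuity", {
  sys <- make_sphere_system(2, 2, solv5, grid_side = 60, softcore_side = 0)
  rep_ <- switch_discontinuity(sys$s1, sys$s2, solv5)
  expect_equal(rep_$switch_radius, 30)
  # just inside, roughly half the charge shell is beyond the isotropic cutoff,
  # so the jump is a sizeable fraction of the energy; the diagnostic must see it
  expect_gt(abs(rep_$jump), 0.1 * abs(rep_$outside))
  expect_lt(abs(rep_$jump), 1.5 * abs(rep_$outside))
})

test_that("requesting a term with a missing grid errors by name", {
  s <- bare_sphere(6, 1)
  expect_error(pair_energy(s, s, pos2 = c(20, 0, 0), solvent = solv5,
                           terms = "softcore"), "softcore")
  expect_error(pair_energy(s, s, pos2 = c(20, 0, 0), solvent = solv5,
                           terms = "edesolv"), "edesolv")
})

test_that("forces vanish in a constant potential and match -dw/dr in the DH regime", {
  # constant electrostatic grid: zero force everywhere inside
  g <- ramp_grid(n = 9, spacing = 2, f = function(x, y, z) 3.7)
  s <- solute(atom_set(matrix(0, 1, 3), charges = 1, radii = 1),
              stokes_radius = 2, grids = list(electrostatic = g))
  ft <- pair_forces_torques(s, s, pos2 = c(4, 1, 0), solvent = solv5, use_dh = FALSE)
  expect_equal(ft$force2, c(0, 0, 0), tolerance = 1e-10)
  # DH regime: finite differences reproduce the analytic derivative to O(delta^2)
  s1 <- bare_sphere(6, 3); s2 <- bare_sphere(6, -2)
  pair <- dh_pair(3, -2, 12, solv5)
  d <- 47
  ft <- pair_forces_torques(s1, s2, pos2 = c(d, 0, 0), solvent = solv5, delta = 0.05)
  expect_equal(ft$force2[1], -dh_pmf_deriv(d, pair), tolerance = 1e-5)
  expect_equal(ft$force2[2:3], c(0, 0), tolerance = 1e-10)
  # Newton's third law
  expect_equal(ft$force1, -ft$force2)
  expect_equal(ft$torque1, c(0, 0, 0), tolerance = 1e-9)
})

test_that("soft-core grids follow the inverse-power law and the atom-sum oracle", {
  atoms <- atom_set(matrix(c(0, 0, 0), 1, 3), radii = 1)
  g1 <- softcore_from_atoms(atoms, side = 16, spacing = 0.5, exponent = 1)
  # power law: value halves when the distance doubles (n = 1, single atom)
  expect_equal(grid_value(g1, c(2, 0, 0)) / grid_value(g1, c(4, 0, 0)), 2,
               tolerance = 1e-9)
  # far from all atoms the potential is ~0
  g6 <- softcore_from_atoms(atoms, side = 16, spacing = 0.5, exponent = 6)
  expect_lt(grid_value(g6, c(7.5, 0, 0)), 1e-4)
  # probe equals the direct atom-sum for a multi-atom set
  set.seed(12)
  multi <- atom_set(matrix(runif(15, -2, 2), 5, 3), radii = runif(5, 0.8, 1.6))
  gm <- softcore_from_atoms(multi, side = 12, spacing = 0.5, exponent = 6,
                            epsilon = 0.4)
  probe_node <- gm$origin + c(9, 11, 13) * gm$spacing   # a lattice node
  oracle <- sum(0.4 * (multi$radii /
    sqrt(rowSums(sweep(multi$positions, 2, probe_node)^2)))^6)
  expect_equal(grid_value(gm, probe_node), min(oracle, 100), tolerance = 1e-9)
})

test_that("the R pair energy agrees with the compiled kernel", {
  sys <- make_sphere_system(3, -2, solv5, grid_side = 40, softcore_side = 16)
  set.seed(77)
  for (i in 1:5) {
    d <- c(13 + 25 * runif(1), runif(2, -5, 5))
    q1 <- quat_normalize(rnorm(4)); q2 <- quat_normalize(rnorm(4))
    pe <- pair_energy(sys$s1, sys$s2, pos2 = d, quat1 = q1, quat2 = q2,
                      solvent = solv5)
    cp <- gridbd:::cpp_pair_terms(gridbd:::solute_cdata(sys$s1),
                                  gridbd:::solute_cdata(sys$s2),
                                  q1, q2, d, solv5$kappa,
                                  solv5$relative_permittivity, TRUE, Inf)
    expect_equal(pe$total, sum(cp), tolerance = 1e-10)
    expect_equal(pe$electrostatic_grid, unname(cp["electrostatic_grid"]),
                 tolerance = 1e-10)
    expect_equal(pe$softcore, unname(cp["softcore"]), tolerance = 1e-10)
  }
})
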