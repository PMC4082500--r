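test_that("random displacements have the prescribed moments", {
  expect_equal(random_displacement(0, 0.5), c(0, 0, 0))
  set.seed(31)
  D <- 0.04; dt <- 0.5
  x <- matrix(rnorm(0), 0, 3)
  draws <- t(replicate(30000, random_displacement(D, dt)))
  v <- 2 * D * dt
  n <- length(draws)
  # mean 0 within 4 sigma
  expect_lt(abs(mean(draws)), 4 * sqrt(v / n))
  # per-component variance within the 4-sigma chi^2 interval
  s2 <- mean(draws^2)
  expect_lt(abs(s2 - v), 4 * v * sqrt(2 / n))
})

test_that("the drift term of the translation step is exactly D F dt / kBT", {
  expect_equal(bd_translation_step(c(1, 2, 3), c(0, 0, 0), 0, 0.5, 0.6),
               c(1, 2, 3))
  p <- bd_translation_step(c(0, 0, 0), c(2, -1, 0.5), D = 0.04, dt = 0.5,
                           kBT = 0.59616, noise = FALSE)
  expect_equal(p, 0.04 / 0.59616 * c(2, -1, 0.5) * 0.5, tolerance = 1e-12)
  expect_error(bd_translation_step(c(0, 0, 0), c(Inf, 0, 0), 0.04, 0.5, 0.6),
               "non-finite")
})

test_that("the rotation step is the identity for zero torque and zero Dr", {
  q <- quat_normalize(c(0.8, 0.1, -0.5, 0.2))
  expect_equal(bd_rotation_step(q, c(0, 0, 0), 0, 0.5, 0.6), q, tolerance = 1e-12)
  set.seed(32)
  q2 <- bd_rotation_step(q, c(1, 2, 3), 1e-3, 0.5, 0.6)
  expect_equal(sum(q2^2), 1, tolerance = 1e-12)
  expect_error(bd_rotation_step(q, c(NaN, 0, 0), 1e-3, 0.5, 0.6), "non-finite")
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  s <- bare_sphere(6, 2)
  run <- function() {
    p <- bd_params(dt = 0.5, n_steps = 300, record_every = 5, seed = 99,
                   use_dh = TRUE)
    simulate_bd(s, n_copies = 8, box = box_spec(150), solvent = solv5,
                params = p)
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$quaternions, t2$quaternions)
  expect_identical(t1$energies, t2$energies)
})

test_that("free-diffusion MSD is linear with slope 6 D0", {
  s <- bare_sphere(6, 0)
  p <- bd_params(dt = 0.5, n_steps = 1500, record_every = 1, seed = 41,
                 use_dh = FALSE, use_hydro = FALSE)
  traj <- simulate_bd(s, n_copies = 100, box = box_spec(400), solvent = solv5,
                      params = p)
  D0 <- stokes_einstein_d0(6, 300, 0.89)$Dt
  res <- long_time_self_diffusion(traj, fit_window = c(0.01, 0.1),
                                  skip_fraction = 0)
  expect_equal(res$D, D0, tolerance = 0.05)
  # linearity: slope fitted on a disjoint window agrees
  res2 <- long_time_self_diffusion(traj, fit_window = c(0.2, 0.5),
                                   skip_fraction = 0)
  expect_equal(res2$D, D0, tolerance = 0.15)
})

test_that("free rotation decorrelates as exp(-2 Dr t)", {
  at <- atom_set(matrix(c(3, 0, 0), 1, 3), charges = 0, radii = 1)
  s <- solute(at, stokes_radius = 6)
  p <- bd_params(dt = 0.5, n_steps = 2000, record_every = 5, seed = 43,
                 use_dh = FALSE, use_hydro = FALSE)
  traj <- simulate_bd(s, n_copies = 400, box = box_spec(400), solvent = solv5,
                      params = p)
  Dr <- stokes_einstein_d0(6, 300, 0.89)$Dr
  z0 <- t(vapply(seq_len(400), function(i)
    as.numeric(quat_to_matrix(traj$quaternions[i, , 1]) %*% c(0, 0, 1)),
    numeric(3)))
  for (k in c(41, 161)) {
    zk <- t(vapply(seq_len(400), function(i)
      as.numeric(quat_to_matrix(traj$quaternions[i, , k]) %*% c(0, 0, 1)),
      numeric(3)))
    ct <- mean(rowSums(z0 * zk))
    tau <- traj$times[k] - traj$times[1]
    expect_equal(ct, exp(-2 * Dr * tau), tolerance = 0.12)
  }
})

test_that("random rotations sample orientations uniformly", {
  # after free rotational diffusion well past the decorrelation time, the
  # z-component of a body axis must be Uniform(-1, 1)
  at <- atom_set(matrix(c(3, 0, 0), 1, 3), charges = 0, radii = 1)
  s <- solute(at, stokes_radius = 3)   # fast rotation
  p <- bd_params(dt = 0.5, n_steps = 1500, record_every = 750 * 0.5, seed = 44,
                 use_dh = FALSE, use_hydro = FALSE)
  traj <- simulate_bd(s, n_copies = 500, box = box_spec(600), solvent = solv5,
                      params = p)
  nf <- n_frames(traj)
  z <- vapply(seq_len(500), function(i)
    (quat_to_matrix(traj$quaternions[i, , nf]) %*% c(0, 0, 1))[3], numeric(1))
  ks <- suppressWarnings(stats::ks.test(z, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-term energies sum to the recorded total each frame", {
  sys <- make_sphere_system(4, -3, solv5, grid_side = 30, softcore_side = 16)
  p <- bd_params(dt = 0.5, n_steps = 200, record_every = 2.5, seed = 45)
  traj <- simulate_bd(list(sys$s1, sys$s2), n_copies = c(3, 3),
                      box = box_spec(120), solvent = solv5, params = p)
  e <- traj$energies
  resid <- e$total - (e$electrostatic_grid + e$dh_tail + e$edesolv +
                        e$npdesolv + e$softcore)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("soft-core repulsion keeps uncharged spheres apart", {
  atoms <- atom_set(gridbd:::fibonacci_sphere(40, 5), radii = 1.5)
  sc <- softcore_from_atoms(atoms, side = 24, spacing = 1, exponent = 6,
                            epsilon = 1)
  s <- solute(atoms, stokes_radius = 5, grids = list(softcore = sc))
  p <- bd_params(dt = 0.5, n_steps = 4000, record_every = 10, seed = 46,
                 use_dh = FALSE, use_hydro = FALSE)
  traj <- simulate_bd(s, n_copies = 2, box = box_spec(40), solvent = solv5,
                      params = p)
  dmin <- min(vapply(seq_len(n_frames(traj)), function(f) {
    d <- wrap_minimum_image(traj$positions[2, , f] - traj$positions[1, , f],
                            traj$box)
    sqrt(sum(d^2))
  }, numeric(1)))
  expect_gt(dmin, 2 * 5 - 2.5)   # never far below contact
})

test_that("impossible placements raise an informative error", {
  expect_error(place_random(30, box_spec(20), radii = 6, max_try = 200),
               "box")
})

test_that("equilibration detection flags stationary but not drifting runs", {
  set.seed(47)
  nf <- 200; N <- 5
  pos <- array(runif(N * 3 * nf, -25, 25), c(N, 3, nf))
  stationary <- synthetic_traj(pos, box_spec(50),
                               energies_total = rnorm(nf, 100, 1))
  res <- detect_equilibration(stationary, n_segments = 10, gr_threshold = 1)
  expect_false(is.na(res$equilibrated_from))
  expect_lt(res$equilibrated_from, stationary$times[nf] / 2)
  drifting <- synthetic_traj(pos, box_spec(50),
                             energies_total = seq(0, 500, length.out = nf) +
                               rnorm(nf, 0, 1))
  res2 <- detect_equilibration(drifting, n_segments = 10, gr_threshold = 1)
  expect_true(is.na(res2$equilibrated_from) ||
                res2$equilibrated_from > drifting$times[nf] / 2)
})

test_that("image counts make unwrapped trajectories continuous", {
  s <- bare_sphere(4, 0)
  p <- bd_params(dt = 0.5, n_steps = 3000, record_every = 0.5, seed = 48,
                 use_dh = FALSE, use_hydro = FALSE)
  traj <- simulate_bd(s, n_copies = 4, box = box_spec(20), solvent = solv5,
                      params = p)
  up <- unwrap_positions(traj)
  step <- abs(up[, , -1] - up[, , -dim(up)[3]])
  # free-diffusion steps are a few sigma at most; boundary jumps would be ~20 A
  expect_lt(max(step), 8 * sqrt(2 * max(traj$D0t) * p$dt) + 0.5)
})
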