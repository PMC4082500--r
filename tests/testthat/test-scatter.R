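test_that("g(r) is flat for an ideal gas and sharp for a fixed pair", {
  set.seed(61)
  nf <- 60; N <- 40; side <- 60
  pos <- array(runif(N * 3 * nf, -side / 2, side / 2), c(N, 3, nf))
  traj <- synthetic_traj(pos, box_spec(side))
  prof <- radial_distribution(traj, bin_width = 2, skip_fraction = 0)
  mid <- prof$g[prof$r > 6 & prof$r < 28]
  expect_lt(max(abs(mid - 1)), 0.25)
  expect_lt(abs(mean(mid) - 1), 0.05)
  # two fixed particles at distance d: a single populated bin
  two <- array(0, c(2, 3, 1)); two[2, 1, 1] <- 17.2
  t2 <- synthetic_traj(two, box_spec(60))
  p2 <- radial_distribution(t2, bin_width = 1, skip_fraction = 0)
  expect_equal(which(p2$counts > 0), 18L)    # bin [17, 18)
  expect_error(radial_distribution(t2, r_max = 40), "half the box")
})

test_that("hard-sphere-like configurations show an excluded core and g -> 1", {
  # independent Metropolis Monte Carlo of hard spheres as the oracle
  set.seed(62)
  N <- 30; sigma <- 6; side <- 62
  box <- box_spec(side)
  pos <- place_random(N, box, radii = sigma / 2)
  ok_move <- function(pos, i, p) {
    for (j in seq_len(N)[-i]) {
      if (sqrt(sum(wrap_minimum_image(p - pos[j, ], box)^2)) < sigma) return(FALSE)
    }
    TRUE
  }
  frames <- list(); f <- 0
  for (sweep in 1:600) {
    for (i in 1:N) {
      p <- pos[i, ] + runif(3, -1.5, 1.5)
      p <- p - side * floor(p / side + 0.5)
      if (ok_move(pos, i, p)) pos[i, ] <- p
    }
    if (sweep > 100 && sweep %% 10 == 0) { f <- f + 1; frames[[f]] <- pos }
  }
  arr <- array(unlist(frames), c(N, 3, f))
  prof <- radial_distribution(synthetic_traj(arr, box), bin_width = 1,
                              skip_fraction = 0)
  expect_true(all(prof$g[prof$r < sigma - 0.5] == 0))
  outer <- prof$g[prof$r > 1.6 * sigma & prof$r < side / 2 - 2]
  expect_lt(abs(mean(outer) - 1), 0.1)
})

test_that("S(q) is identically 1 when h is zero and matches a closed form", {
  r <- seq(0.25, 200, by = 0.5)
  flat <- structure(data.frame(r = r, g = rep(1, length(r)), counts = 0),
                    number_density = 1e-4, bin_width = 0.5,
                    class = c("radial_profile", "data.frame"))
  q <- seq(0, 0.3, length.out = 40)
  S <- structure_factor(flat, q = q)
  expect_equal(S$S, rep(1, 40), tolerance = 1e-12)
  # exponential total correlation: h = exp(-r/xi) has the transform
  # int h sin(qr)/(qr) r^2 dr = 2 xi^3 / (1 + q^2 xi^2)^2
  xi <- 8; np <- 2e-4
  expo <- structure(data.frame(r = r, g = 1 + exp(-r / xi), counts = 0),
                    number_density = np, bin_width = 0.5,
                    class = c("radial_profile", "data.frame"))
  Se <- structure_factor(expo, q = q)
  expect_equal(Se$S, 1 + 4 * pi * np * 2 * xi^3 / (1 + q^2 * xi^2)^2,
               tolerance = 1e-3)
  # the q -> 0 limit is the compressibility combination
  dr <- 0.5
  expect_equal(structure_factor(expo, q = 0)$S,
               1 + 4 * pi * np * sum(exp(-r / xi) * r^2 * dr), tolerance = 1e-9)
})

test_that("g(r)-route S(q) agrees with the direct Debye double sum", {
  set.seed(63)
  N <- 80; side <- 50
  pos <- matrix(runif(N * 3, -side / 2, side / 2), N, 3)
  prof <- radial_distribution(pos, bin_width = 0.05,
                              r_max = side * sqrt(3), volume = side^3)
  q <- seq(0.12, 0.8, length.out = 25)
  S_gr <- structure_factor(prof, q = q, number_density = N / side^3)$S
  # independent oracle: the Debye double sum sum_{i<j} sin(q d_ij)/(q d_ij),
  # with the exact finite-system bookkeeping of the histogram route (pair
  # normalization uses N(N-1)/2, and the ideal gas is subtracted over the
  # finite histogram range)
  dmat <- as.matrix(dist(pos)); dij <- dmat[upper.tri(dmat)]
  rmax <- max(prof$r) + 0.025
  S_oracle <- vapply(q, function(qq) {
    ideal <- 4 * pi * (N / side^3) *
      integrate(function(r) sin(qq * r) / (qq * r) * r^2, 0, rmax,
                subdivisions = 400)$value
    1 + 2 / (N - 1) * sum(sin(qq * dij) / (qq * dij)) - ideal
  }, numeric(1))
  expect_lt(max(abs(S_gr - S_oracle)), 0.02)
})

test_that("the oblate form factor is normalized and degenerates to the sphere", {
  expect_identical(oblate_form_factor(0, 17.5, 47.4), 1)
  q <- seq(0.01, 0.3, length.out = 12)
  R <- 20
  sph <- (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
  expect_equal(oblate_form_factor(q, R, R), sph, tolerance = 1e-8)
  expect_error(oblate_form_factor(0.1, -1, 5), "> 0")
})

test_that("the oblate form factor matches a fine-grid orientational average", {
  a <- 17.5; b <- 47.4
  alpha <- (seq_len(20000) - 0.5) / 20000 * pi / 2
  for (qq in c(0.02, 0.07, 0.15)) {
    u <- qq * sqrt(a^2 * cos(alpha)^2 + b^2 * sin(alpha)^2)
    amp <- (3 * (sin(u) - u * cos(u)) / u^3)^2
    riemann <- sum(amp * sin(alpha)) * (pi / 2 / 20000)
    expect_equal(oblate_form_factor(qq, a, b), riemann, tolerance = 1e-5)
  }
})

test_that("the normalized intensity is the elementwise product P * S", {
  q <- seq(0.01, 0.2, length.out = 30)
  P <- oblate_form_factor(q, 17.5, 47.4)
  S <- 1 + 0.3 * sin(40 * q) / (40 * q)
  out <- normalized_intensity(q, P, S)
  expect_equal(out$I_norm, P * S)
  expect_equal(normalized_intensity(q, P, rep(1, 30))$I_norm, P)
  expect_equal(normalized_intensity(q, rep(1, 30), S)$I_norm, S)
  expect_error(normalized_intensity(q, P, S[-1]), "match")
  Sdf <- data.frame(q = q + 1e-3, S = S)
  expect_error(normalized_intensity(q, P, Sdf), "match")
})

test_that("g(r) convergence flags stationary runs and rejects drifting ones", {
  set.seed(64)
  nf <- 200; N <- 30; side <- 60
  pos <- array(runif(N * 3 * nf, -side / 2, side / 2), c(N, 3, nf))
  stat_traj <- synthetic_traj(pos, box_spec(side))
  rep_ok <- gr_convergence(stat_traj, n_segments = 10, threshold = 0.5,
                           bin_width = 2)
  expect_true(rep_ok$converged)
  # drifting density: particles collapse toward the origin over time
  shrink <- array(0, c(N, 3, nf))
  for (f in seq_len(nf)) shrink[, , f] <- pos[, , f] * (1 - 0.9 * f / nf)
  drift_traj <- synthetic_traj(shrink, box_spec(side))
  rep_bad <- gr_convergence(drift_traj, n_segments = 10, threshold = 0.5,
                            bin_width = 2)
  expect_false(rep_bad$converged)
  expect_gt(rep_bad$max_deviation, rep_ok$max_deviation)
})

test_that("segment scatter shrinks with segment length", {
  set.seed(65)
  nf <- 240; N <- 30; side <- 60
  pos <- array(runif(N * 3 * nf, -side / 2, side / 2), c(N, 3, nf))
  traj <- synthetic_traj(pos, box_spec(side))
  few <- gr_convergence(traj, n_segments = 6, bin_width = 2)
  many <- gr_convergence(traj, n_segments = 24, bin_width = 2)
  # 4x shorter segments -> about 2x larger per-bin SD
  sel <- few$full$r > 10 & few$full$r < 28
  ratio <- mean(many$segment_sd[sel]) / mean(few$segment_sd[sel])
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("self-diffusion is zero for a frozen trajectory and validates windows", {
  frozen <- synthetic_traj(array(rep(matrix(rnorm(30), 10, 3), 50),
                                 c(10, 3, 50)), box_spec(100))
  res <- long_time_self_diffusion(frozen, skip_fraction = 0)
  expect_equal(res$D, 0, tolerance = 1e-12)
  expect_error(long_time_self_diffusion(frozen, fit_window = c(2, 3),
                                        skip_fraction = 0), "window")
  tiny <- synthetic_traj(array(rnorm(10 * 3 * 3), c(10, 3, 3)), box_spec(100))
  expect_error(long_time_self_diffusion(tiny, skip_fraction = 0), "few frames")
})
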