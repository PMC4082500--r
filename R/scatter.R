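# Solution observables from trajectories: radial distribution function,
# structure factor by Fourier transformation of h(r) = g(r) - 1, form
# factors, normalized small-angle scattering intensity, g(r) convergence,
# and the long-time self-diffusion coefficient.

# pair-distance histogram for one configuration
pair_distances <- function(pos, box = NULL) {
  n <- nrow(pos)
  d <- numeric(n * (n - 1) / 2)
  k <- 1L
  for (i in seq_len(n - 1)) {
    rel <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    if (!is.null(box) && box$periodic) rel <- wrap_minimum_image(rel, box)
    m <- nrow(rel)
    d[k:(k + m - 1)] <- sqrt(rowSums(rel^2))
    k <- k + m
  }
  d
}

#' Radial distribution function
#'
#' Center-to-center pair histogram normalized by the ideal-gas shell counts.
#' For periodic trajectories `r_max` may not exceed half the box.
#'
#' @param x a `bd_trajectory`, or an n x 3 matrix of centers (single
#'   configuration).
#' @param bin_width bin width (A, default 1).
#' @param r_max histogram range (A; default half the box for periodic input).
#' @param skip_fraction fraction of initial frames discarded as
#'   equilibration (trajectory method; default the run's
#'   `equilibration_fraction`).
#' @param box a [box_spec()] (matrix method; NULL treats the configuration
#'   as open and requires an explicit `volume`).
#' @param volume system volume (A^3) for the open (non-periodic) case.
#' @param ... unused.
#' @return object of class `radial_profile`: data.frame with bin centers
#'   `r`, `g`, raw pair `counts`; attributes `number_density`, `bin_width`,
#'   `n_frames`.
#' @export
radial_distribution <- function(x, ...) UseMethod("radial_distribution")

rd_core <- function(dist_list, n, vol, bin_width, r_max, box = NULL) {
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  counts <- numeric(nb)
  for (d in dist_list) {
    d <- d[d < nb * bin_width]
    counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L, nb), nbins = nb)
  }
  nf <- length(dist_list)
  centers <- edges[-1] - bin_width / 2
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  np <- n / vol
  ideal <- nf * n * (n - 1) / 2 * shell / vol
  g <- ifelse(ideal > 0, counts / ideal, 0)
  structure(data.frame(r = centers, g = g, counts = counts),
            number_density = np, bin_width = bin_width, n_frames = nf,
            class = c("radial_profile", "data.frame"))
}

#' @rdname radial_distribution
#' @export
radial_distribution.bd_trajectory <- function(x, bin_width = 1, r_max = NULL,
                                              skip_fraction = NULL, ...) {
  if (n_solutes(x) < 2) stop("need at least 2 solutes")
  if (is.null(skip_fraction)) skip_fraction <- x$params$equilibration_fraction
  if (is.null(r_max)) r_max <- x$box$side / 2
  if (x$box$periodic && r_max > x$box$side / 2 + 1e-9)
    stop("r_max must not exceed half the box side")
  frames <- seq_len(n_frames(x))
  frames <- frames[frames > skip_fraction * length(frames)]
  dl <- lapply(frames, function(f)
    pair_distances(x$positions[, , f, drop = TRUE], x$box))
  rd_core(dl, n_solutes(x), x$box$side^3, bin_width, r_max)
}

#' @rdname radial_distribution
#' @export
radial_distribution.matrix <- function(x, bin_width = 1, r_max = NULL,
                                       box = NULL, volume = NULL, ...) {
  if (nrow(x) < 2) stop("need at least 2 solutes")
  if (!is.null(box) && box$periodic) {
    vol <- box$side^3
    if (is.null(r_max)) r_max <- box$side / 2
    if (r_max > box$side / 2 + 1e-9) stop("r_max must not exceed half the box side")
  } else {
    if (is.null(volume)) stop("open configurations need an explicit volume")
    vol <- volume
    if (is.null(r_max)) stop("open configurations need an explicit r_max")
  }
  rd_core(list(pair_distances(x, box)), nrow(x), vol, bin_width, r_max)
}

#' Static structure factor from a radial profile
#'
#' Fourier transformation of the total correlation function,
#' `S(q) = 1 + 4 pi n_p int h(r) sin(qr)/(qr) r^2 dr`, evaluated by the
#' trapezoidal rule up to the profile's range; `q = 0` uses the
#' `sin(x)/x -> 1` limit, so `S(0)` is the compressibility combination
#' `1 + 4 pi n_p int h r^2 dr`.
#'
#' @param profile a `radial_profile`.
#' @param q scattering-vector magnitudes (1/A); default 200 points over
#'   0.005-0.4 1/A (0.05-4 1/nm).
#' @param number_density override of n_p (1/A^3).
#' @param window `"none"` or `"cosine"` (half-cosine taper over the outer
#'   half of the r range, suppressing truncation ringing).
#' @return data.frame with columns `q` (1/A), `q_nm` (1/nm) and `S`.
#' @export
structure_factor <- function(profile, q = NULL, number_density = NULL,
                             window = c("none", "cosine")) {
  window <- match.arg(window)
  if (is.null(q)) q <- seq(0.005, 0.4, length.out = 200)
  np <- if (is.null(number_density)) attr(profile, "number_density") else number_density
  r <- profile$r
  h <- profile$g - 1
  if (window == "cosine") {
    rmax <- max(r)
    tap <- ifelse(r > rmax / 2, 0.5 * (1 + cos(pi * (r - rmax / 2) / (rmax / 2))), 1)
    h <- h * tap
  }
  dr <- c(diff(r), tail(diff(r), 1))
  S <- vapply(q, function(qq) {
    kern <- if (qq == 0) rep(1, length(r)) else sin(qq * r) / (qq * r)
    1 + 4 * pi * np * sum(h * kern * r^2 * dr)
  }, numeric(1))
  data.frame(q = q, q_nm = q * 10, S = S)
}

#' Orientationally averaged oblate-ellipsoid form factor
#'
#' For an ellipsoid of revolution with semi-axis of revolution `a` and
#' equatorial radius `b`, the orientational average over the angle `alpha`
#' between the scattering vector and the revolution axis of
#' `[3 (sin u - u cos u)/u^3]^2` with
#' `u = q sqrt(a^2 cos^2 alpha + b^2 sin^2 alpha)`, weighted by
#' `sin(alpha)`.  Normalized so that `P(0) = 1`; `a = b` recovers the
#' homogeneous-sphere form factor.
#'
#' @param q scattering-vector magnitudes (1/A); vectorized.
#' @param a semi-axis of revolution (A).
#' @param b equatorial semi-axis (A).
#' @return `P(q)` values.
#' @export
oblate_form_factor <- function(q, a, b) {
  if (!(a > 0) || !(b > 0)) stop("a and b must be > 0")
  vapply(q, function(qq) {
    if (qq == 0) return(1)
    integrand <- function(alpha) {
      u <- qq * sqrt(a^2 * cos(alpha)^2 + b^2 * sin(alpha)^2)
      sphere_amplitude(u)^2 * sin(alpha)
    }
    integrate(integrand, 0, pi / 2, rel.tol = 1e-10)$value
  }, numeric(1))
}

# 3 (sin u - u cos u)/u^3 with a stable small-u series
sphere_amplitude <- function(u) {
  small <- abs(u) < 1e-3
  out <- numeric(length(u))
  out[small] <- 1 - u[small]^2 / 10 + u[small]^4 / 280
  ub <- u[!small]
  out[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  out
}

#' Normalized small-angle scattering intensity
#'
#' `I(q)/(A n_p) = P(q) S(q)`: the elementwise product of the form factor
#' and structure factor on a common q grid.
#'
#' @param q q grid (1/A).
#' @param P form-factor values on `q`.
#' @param S structure-factor values on `q` (or a data.frame from
#'   [structure_factor()]; its grid must match `q` exactly).
#' @return data.frame with `q`, `P`, `S` and `I_norm`.
#' @export
normalized_intensity <- function(q, P, S) {
  if (is.data.frame(S)) {
    if (length(S$q) != length(q) || any(abs(S$q - q) > 1e-12))
      stop("q grids of P and S do not match")
    S <- S$S
  }
  if (length(P) != length(q) || length(S) != length(q))
    stop("q grids of P and S do not match")
  data.frame(q = q, P = P, S = S, I_norm = P * S)
}

#' g(r) convergence report
#'
#' Compares the full-trajectory g(r) with g(r) computed over `n_segments`
#' sequential trajectory segments.  The deviation statistic is, per
#' segment, the count-weighted mean absolute difference from the full
#' curve (weighting by the expected ideal-gas counts suppresses the noise
#' of nearly empty small-r bins); the reported `max_deviation` is its
#' maximum over segments, so a drift that any segment sees flags the run.
#'
#' @param traj a `bd_trajectory`.
#' @param n_segments number of sequential segments (default 20).
#' @param threshold maximum allowed deviation for the `converged` flag.
#' @param bin_width,r_max histogram parameters (defaults as in
#'   [radial_distribution()]).
#' @param skip_fraction initial fraction discarded first.
#' @return list with `full` and `segment_mean` profiles, per-bin `segment_sd`,
#'   `max_deviation` and `converged`.
#' @export
gr_convergence <- function(traj, n_segments = 20, threshold = 0.15,
                           bin_width = 1, r_max = NULL, skip_fraction = 0) {
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  frames <- frames[frames > skip_fraction * nf]
  if (length(frames) < n_segments)
    stop("too few frames to form the requested segments")
  if (is.null(r_max)) r_max <- traj$box$side / 2
  seg <- split(frames, cut(seq_along(frames), n_segments, labels = FALSE))
  gmat <- vapply(seg, function(ix) {
    dl <- lapply(ix, function(f) pair_distances(traj$positions[, , f, drop = TRUE], traj$box))
    rd_core(dl, n_solutes(traj), traj$box$side^3, bin_width, r_max)$g
  }, numeric(ceiling(r_max / bin_width)))
  dl <- lapply(frames, function(f) pair_distances(traj$positions[, , f, drop = TRUE], traj$box))
  full <- rd_core(dl, n_solutes(traj), traj$box$side^3, bin_width, r_max)
  seg_mean <- rowMeans(gmat)
  seg_sd <- apply(gmat, 1, sd)
  # ideal-gas count weights for the deviation statistic
  edges <- seq(0, length(full$r)) * bin_width
  w <- edges[-1]^3 - edges[-length(edges)]^3
  seg_dev <- apply(gmat, 2, function(g) sum(w * abs(g - full$g)) / sum(w))
  maxdev <- max(seg_dev)
  list(full = full, segment_mean = seg_mean, segment_sd = seg_sd,
       segment_deviation = seg_dev,
       max_deviation = maxdev, converged = maxdev <= threshold)
}

#' Long-time self-diffusion coefficient from a trajectory
#'
#' Ensemble mean-squared displacement of the unwrapped centers over a set
#' of lag times (averaged over time origins), fitted by least squares over
#' the window `fit_window` (fractions of the maximum lag); the long-time
#' coefficient is the slope divided by 6.
#'
#' @param traj a `bd_trajectory`.
#' @param fit_window `c(lo, hi)` fractions of the trajectory length
#'   (default `c(0.1, 0.5)`).
#' @param skip_fraction initial fraction discarded as equilibration
#'   (default the run's setting).
#' @param D0 reference infinite-dilution coefficient for the normalized
#'   ratio (default: the run's mean Stokes-Einstein D0).
#' @return list with `D` (A^2/ps), `ratio` = D/D0, and the `msd` data.frame.
#' @export
long_time_self_diffusion <- function(traj, fit_window = c(0.1, 0.5),
                                     skip_fraction = NULL, D0 = NULL) {
  if (is.null(skip_fraction)) skip_fraction <- traj$params$equilibration_fraction
  if (is.null(D0)) D0 <- mean(traj$D0t)
  up <- unwrap_positions(traj)
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  frames <- frames[frames > skip_fraction * nf]
  up <- up[, , frames, drop = FALSE]
  tt <- traj$times[frames]
  nlag <- length(frames) - 1
  if (nlag < 4) stop("fit window outside the trajectory: too few frames")
  lags <- seq_len(nlag)
  msd <- vapply(lags, function(L) {
    o <- seq(1, length(frames) - L, by = max(1L, L %/% 4L))  # stride origins
    mean(vapply(o, function(s)
      mean(rowSums((up[, , s + L] - up[, , s])^2)), numeric(1)))
  }, numeric(1))
  tau <- tt[1 + lags] - tt[1]
  lo <- fit_window[1] * max(tau); hi <- fit_window[2] * max(tau)
  sel <- tau >= lo & tau <= hi
  if (sum(sel) < 2) stop("fit window outside the trajectory")
  fit <- lm(msd[sel] ~ tau[sel])
  D <- unname(coef(fit)[2]) / 6
  list(D = D, ratio = D / D0, msd = data.frame(tau = tau, msd = msd),
       fit_window = c(lo, hi), D0 = D0)
}
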