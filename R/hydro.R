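# Mean-field hydrodynamics: local volume fractions and volume-fraction
# dependent short-time diffusion coefficients.
#
# Model coefficients (pinned so they can be audited against the original
# publications):
#   Tokuyama-Oppenheim hard-sphere suspension, short-time translational:
#     D_t^short/D0 = 1/(1 + H(phi)),
#     H = 2 b^2/(1-b) - c/(1+2c) - b c (2+c)/((1+c)(1-b+c)),
#     b = sqrt(9 phi / 8), c = 11 phi / 16.
#   Cichocki-Ekiel-Jezewska-Wajnryb short-time rotational virial series with
#   lubrication and two-/three-body terms:
#     D_r^short/D0 = 1 - 0.631 phi - 0.726 phi^2.

#' Short-time translational diffusion ratio (Tokuyama model)
#'
#' Hard-sphere suspension with direct and hydrodynamic interactions.
#' Equals 1 at infinite dilution and decreases strictly with the local
#' volume fraction.
#'
#' @param phi local volume fraction, in `[0, 0.64)`.
#' @return `D_t^short / D0` in `(0, 1]` (vectorized).
#' @export
tokuyama_dt_short <- function(phi) {
  if (any(phi < 0 | phi >= 0.64)) stop("phi must lie in [0, 0.64)")
  vapply(phi, cpp_tokuyama, numeric(1))
}

#' Short-time rotational diffusion ratio (Cichocki et al. model)
#'
#' Virial series including lubrication plus two- and three-body mobility
#' terms.
#'
#' @param phi local volume fraction, in `[0, 0.64)`.
#' @return `D_r^short / D0` (vectorized).
#' @export
cichocki_dr_short <- function(phi) {
  if (any(phi < 0 | phi >= 0.64)) stop("phi must lie in [0, 0.64)")
  vapply(phi, cpp_cichocki, numeric(1))
}

#' Intersection (lens) volume of two spheres
#'
#' Standard two-sphere lens: the full smaller-sphere volume when one sphere
#' contains the other, zero when disjoint.
#'
#' @param d center-to-center distance (A, >= 0).
#' @param r1,r2 sphere radii (A, >= 0).
#' @return volume in A^3 (vectorized over `d`).
#' @export
sphere_cap_intersection_volume <- function(d, r1, r2) {
  if (any(d < 0) || r1 < 0 || r2 < 0) stop("d, r1, r2 must be >= 0")
  vapply(d, function(dd) cpp_lens_volume(dd, r1, r2), numeric(1))
}

#' Local volume fraction around a solute
#'
#' The local volume is the sphere of radius `R_cut` centered on solute `i`;
#' neighbors entirely inside (center distance below `R_cut - sigma_j`)
#' contribute their full volume, partially included neighbors contribute the
#' lens volume of their sphere with the local sphere.  Whether the central
#' solute's own volume counts is controlled by `include_self` (default
#' FALSE).
#'
#' @param positions n x 3 matrix of solute centers (A).
#' @param stokes_radii,volumes per-solute Stokes radii (A) and volumes (A^3).
#' @param i index of the central solute.
#' @param R_cut local-volume radius (A, must exceed every Stokes radius).
#' @param box optional [box_spec()] for minimum-image distances.
#' @param include_self count the central solute's own volume?
#' @return the local volume fraction `phi_i`.
#' @export
local_volume_fraction <- function(positions, stokes_radii, volumes, i, R_cut,
                                  box = NULL, include_self = FALSE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (length(stokes_radii) == 1) stokes_radii <- rep(stokes_radii, n)
  if (length(volumes) == 1) volumes <- rep(volumes, n)
  if (!(R_cut > max(stokes_radii))) stop("R_cut must exceed the largest Stokes radius")
  occ <- if (include_self) volumes[i] else 0
  for (j in seq_len(n)[-i]) {
    d <- positions[j, ] - positions[i, ]
    if (!is.null(box) && box$periodic) d <- wrap_minimum_image(d, box)
    dd <- sqrt(sum(d^2))
    if (dd >= R_cut + stokes_radii[j]) next
    occ <- occ + if (dd < R_cut - stokes_radii[j]) volumes[j]
                 else cpp_lens_volume(dd, R_cut, stokes_radii[j])
  }
  occ / (4 / 3 * pi * R_cut^3)
}

#' Local-volume cutoff used in simulations
#'
#' Four times the side of the largest interaction grid, rescaled to half the
#' box when the box is small.
#'
#' @param solutes list of [solute()]s.
#' @param box a [box_spec()].
#' @return R_cut in A.
#' @export
local_volume_cutoff <- function(solutes, box) {
  sides <- unlist(lapply(solutes, function(s)
    vapply(s$grids, function(g) max((g$shape - 1) * g$spacing), numeric(1))))
  rc <- if (length(sides)) 4 * max(sides) else box$side / 2
  min(rc, box$side / 2)
}
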