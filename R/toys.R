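# Toy systems: the planar two-timescale four-state system that reduces to
# extended model free, the two-distance exchange system used to study
# distance averaging, and a synthetic multi-proton ensemble generator.

#' Four-state planar toy system with two timescales of angular motion
#'
#' Builds the classic validation system for multi-timescale angular
#' dynamics: a unit-length two-atom vector rotating in a plane between two
#' slowly interconverting macrostates, each split into two quickly
#' interconverting microstates.  The fast angle `theta_f` follows from the
#' two-site closed form `S2 = (1 + 3 cos^2 theta)/4`; the slow angle
#' `theta_s` is solved numerically (bisection to 1e-12) so that the overall
#' tensor-average order parameter equals `S_f2 * S_s2`.
#'
#' @param S_f2 fast-timescale order parameter, in `[0.25, 1]`.
#' @param S_s2 slow-timescale order parameter; the overall `S_f2 * S_s2`
#'   must stay above the planar two-site limit.
#' @return a `ke_geometry` with four unit vectors (uniform populations) and
#'   attributes `theta_f`, `theta_s` (radians).
#' @export
build_emf_toy <- function(S_f2, S_s2) {
  if (S_f2 < 0.25 || S_f2 > 1) stopf("S_f2 must be in [0.25, 1]")
  if (S_s2 < 0 || S_s2 > 1) stopf("S_s2 must be in [0, 1]")
  theta_f <- acos(sqrt((4 * S_f2 - 1) / 3))
  target <- S_f2 * S_s2

  geom_at <- function(theta_s) {
    ang <- c(-theta_s / 2 - theta_f / 2, -theta_s / 2 + theta_f / 2,
             theta_s / 2 - theta_f / 2, theta_s / 2 + theta_f / 2)
    cbind(sin(ang), 0, cos(ang))
  }
  s2_at <- function(theta_s) {
    d <- apply(geom_at(theta_s), 1, dipole_vector)
    sum(rowMeans(d)^2)
  }
  if (target > s2_at(0) + 1e-12) stopf("target order parameter unreachable")
  if (target < s2_at(pi / 2) - 1e-12) {
    stopf("target order parameter %.3f below the planar two-site limit %.3f",
          target, s2_at(pi / 2))
  }
  theta_s <- if (abs(s2_at(0) - target) < 1e-14) 0 else {
    stats::uniroot(function(th) s2_at(th) - target, c(0, pi / 2),
                   tol = 1e-12)$root
  }
  g <- ke_geometry(geom_at(theta_s))
  attr(g, "theta_f") <- theta_f
  attr(g, "theta_s") <- theta_s
  g
}

#' Two-state, two-distance toy system
#'
#' Two states share one internuclear orientation but differ in distance;
#' used to study how the effective distance averaging power moves between
#' `<r^-3>^2` and `<r^-6>` with the exchange timescale.
#'
#' @param r_A,r_B distances in Angstrom.
#' @param p_A population of the first state.
#' @return a `ke_geometry` with two collinear vectors and populations
#'   `(p_A, 1 - p_A)`.
#' @export
build_two_distance_toy <- function(r_A, r_B, p_A) {
  stopifnot(r_A > 0, r_B > 0, p_A >= 0, p_A <= 1)
  ke_geometry(cbind(0, 0, c(r_A, r_B)), populations = c(p_A, 1 - p_A))
}

#' Generate a synthetic proton ensemble
#'
#' Members are Gaussian displacements of a base proton arrangement laid out
#' on a 3 Angstrom lattice; a member is re-drawn (up to 200 times) if any
#' pairwise distance falls below 1.5 Angstrom.  Deterministic for a fixed
#' seed.
#'
#' @param n_members number of conformers (>= 1).
#' @param n_protons number of protons.
#' @param displacement_scale standard deviation of the per-coordinate
#'   displacement, Angstrom.
#' @param seed integer RNG seed.
#' @param spacing base lattice spacing, Angstrom.
#' @return a `ke_ensemble` whose atoms are named `H1 ... Hn` in one
#'   synthetic residue.
#' @export
generate_synthetic_ensemble <- function(n_members, n_protons,
                                        displacement_scale = 0.3,
                                        seed = 1, spacing = 3) {
  stopifnot(n_members >= 1, n_protons >= 2)
  m <- ceiling(n_protons^(1 / 3))
  base <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                z = seq_len(m)))[seq_len(n_protons), ] * spacing
  coords <- array(0, c(n_protons, 3, n_members))
  with_seed(seed, {
    for (k in seq_len(n_members)) {
      for (try in seq_len(200)) {
        xk <- base + matrix(stats::rnorm(3 * n_protons, sd = displacement_scale),
                            ncol = 3)
        if (displacement_scale == 0 || min(stats::dist(xk)) >= 1.5) break
      }
      if (min(stats::dist(xk)) < 1.5) {
        stopf("could not place member %d with all distances >= 1.5 A", k)
      }
      coords[, , k] <- xk
    }
  })
  atoms <- data.frame(
    atom_id = paste0("1.H", seq_len(n_protons)),
    resno = 1L, resname = "SYN",
    atom_name = paste0("H", seq_len(n_protons)),
    stringsAsFactors = FALSE
  )
  ens <- ke_ensemble(atoms, coords)
  ens$rotation_groups <- list()
  ens
}
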