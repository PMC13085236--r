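# Post-convergence diagnostics: spin contamination, spin purification,
# charge-transfer distance and dipole moments, all evaluated on discrete
# weighted point densities (site populations for the model backend, grid
# samples for an external one).

#' Construct a discrete density sample
#'
#' @param points n x 3 matrix of positions (Bohr).
#' @param weights signed density values times integration weights
#'   (electrons per point).
#' @return an object of class \code{density_sample}.
#' @export
density_sample <- function(points, weights) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  if (nrow(points) != length(weights)) stop("points/weights length mismatch")
  if (!all(is.finite(points)) || !all(is.finite(weights)))
    stop("non-finite density sample")
  structure(list(points = points, weights = as.numeric(weights)),
            class = "density_sample")
}

#' Spin contamination of an unrestricted determinant
#'
#' The integral of the negative part of the spin density
#' \eqn{\rho_s = \rho_\uparrow - \rho_\downarrow}:
#' \eqn{c = \int_{\rho_s < 0} -\rho_s(r)\,dr}, here as a sum over sample
#' points.  A spin-mixed open-shell singlet with the unpaired electrons on
#' disjoint fragments has \eqn{c = 1}.
#'
#' @param rho_up,rho_dn \code{density_sample}s on the same point set.
#' @return spin contamination in electrons.
#' @export
spin_contamination <- function(rho_up, rho_dn) {
  if (!isTRUE(all.equal(rho_up$points, rho_dn$points)))
    stop("spin densities sampled on different point sets")
  sum(pmax(0, -(rho_up$weights - rho_dn$weights)))
}

#' Spin-purified energy of a spin-mixed solution
#'
#' \eqn{E_s = 2 E_m - E_t}, removing the triplet contamination of a
#' spin-mixed open-shell singlet energy given the companion triplet energy.
#'
#' @param E_m energy of the spin-mixed solution.
#' @param E_t energy of the triplet solution.
#' @return purified singlet energy.
#' @export
spin_purified_energy <- function(E_m, E_t) {
  2 * E_m - E_t
}

#' Charge-transfer distance and transferred charge
#'
#' From the excited-minus-ground density difference \eqn{\Delta\rho}:
#' the transferred charge \eqn{q_{CT}} is the integral of the positive part
#' of \eqn{\Delta\rho}, and
#' \eqn{d_{CT} = |\int \Delta\rho(r)\, r \, dr| / q_{CT}}
#' (Euclidean norm of the density-difference dipole per transferred
#' electron).
#'
#' @param delta_rho a \code{density_sample} of the density difference.
#' @return list with \code{d_CT} (Bohr) and \code{q_CT} (electrons).
#' @export
ct_distance <- function(delta_rho) {
  q_CT <- sum(pmax(0, delta_rho$weights))
  if (q_CT < 1e-12)
    stop("transferred charge is zero; charge-transfer distance undefined")
  mu <- colSums(delta_rho$points * delta_rho$weights)
  list(d_CT = sqrt(sum(mu^2)) / q_CT, q_CT = q_CT)
}

#' Dipole moment of a charge distribution
#'
#' \eqn{\mu = \sum_p z_p r_p - \sum_k w_k r_k} (atomic units), cores minus
#' electrons.
#'
#' @param rho_total \code{density_sample} of the total electron density.
#' @param core_charges core charges per nucleus/site.
#' @param positions positions of the cores (n x 3, Bohr).
#' @return dipole vector (length 3, a.u.).
#' @export
dipole_moment <- function(rho_total, core_charges, positions) {
  positions <- as.matrix(positions)
  colSums(positions * core_charges) -
    colSums(rho_total$points * rho_total$weights)
}
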