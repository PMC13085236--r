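# Numeric electronic Hessian, saddle-point-order estimation and rotation
# scans.  Model systems are small, so the Hessian is built densely by
# central finite differences of the analytic gradient and diagonalized with
# a full symmetric eigensolver.

#' Numeric electronic Hessian over rotation pairs
#'
#' Central finite differences of the analytic electronic gradient along each
#' nonredundant rotation direction (both spin channels concatenated),
#' symmetrized as \eqn{(H + H^T)/2}.
#'
#' @param state an \code{orbital_state} (any evaluation point).
#' @param backend the backend.
#' @param fd_step finite-difference rotation step (radians).
#' @return list with the symmetric \code{hessian} (Ha), the pair index sets
#'   \code{pairs_up}, \code{pairs_dn}, and the max asymmetry
#'   \code{asymmetry} before symmetrization.
#' @export
numeric_hessian <- function(state, backend, fd_step = 1e-4) {
  pairs_up <- kappa_pairs(state$f_up)
  pairs_dn <- kappa_pairs(state$f_dn)
  n_up <- nrow(pairs_up); n <- n_up + nrow(pairs_dn)
  grad_at <- function(kap_up, kap_dn) {
    st <- apply_unitary(state, kap_up, kap_dn)
    ev <- backend_evaluate(backend, st)
    c(electronic_gradient(mo_hamiltonian(st$C_up, ev$F_up), st$f_up, pairs_up),
      electronic_gradient(mo_hamiltonian(st$C_dn, ev$F_dn), st$f_dn, pairs_dn))
  }
  H <- matrix(0, n, n)
  M <- state$M
  for (k in seq_len(n)) {
    mk <- function(sgn) {
      ku <- matrix(0, M, M); kd <- matrix(0, M, M)
      if (k <= n_up) {
        i <- pairs_up[k, 1]; j <- pairs_up[k, 2]
        ku[i, j] <- sgn * fd_step; ku[j, i] <- -sgn * fd_step
      } else {
        i <- pairs_dn[k - n_up, 1]; j <- pairs_dn[k - n_up, 2]
        kd[i, j] <- sgn * fd_step; kd[j, i] <- -sgn * fd_step
      }
      list(ku, kd)
    }
    kp <- mk(1); km <- mk(-1)
    H[, k] <- (grad_at(kp[[1]], kp[[2]]) - grad_at(km[[1]], km[[2]])) /
      (2 * fd_step)
  }
  asym <- max(abs(H - t(H)))
  list(hessian = (H + t(H)) / 2, pairs_up = pairs_up, pairs_dn = pairs_dn,
       asymmetry = asym)
}

#' Saddle-point order from a Hessian spectrum
#'
#' Number of negative eigenvalues; with a positive magnitude threshold,
#' small negative eigenvalues (|lambda| below the threshold) are excluded,
#' which typically sharpens the estimate at partially relaxed solutions.
#'
#' @param eigs eigenvalues (any unit; threshold in the same unit).
#' @param magnitude_threshold exclusion threshold (0 = count all negatives).
#' @return integer saddle-point order.
#' @export
saddle_order <- function(eigs, magnitude_threshold = 0) {
  if (!length(eigs)) return(0L)
  sum(eigs < 0 & abs(eigs) > magnitude_threshold)
}

#' Saddle-point-order estimate from the diagonal Hessian model
#'
#' Number of negative elements of \eqn{2(\epsilon_i - \epsilon_j)(f_j - f_i)}
#' over the nonredundant pairs of both spins.
#'
#' @param eps_up,eps_dn orbital energies.
#' @param f_up,f_dn occupations.
#' @return integer estimate.
#' @export
diagonal_order_estimate <- function(eps_up, f_up, eps_dn, f_dn) {
  d <- c(diagonal_hessian(eps_up, f_up, kappa_pairs(f_up)),
         diagonal_hessian(eps_dn, f_dn, kappa_pairs(f_dn)))
  sum(d < 0)
}

#' Full saddle-order analysis of a solution
#'
#' @param sol a \code{frdo_solution}.
#' @param backend the backend (rebuilt from \code{sol$spec} if missing).
#' @param magnitude_threshold eigenvalue filter in eV.
#' @param fd_step finite-difference step.
#' @return list of class \code{hessian_report}: \code{eigenvalues} (eV,
#'   ascending), \code{order_all}, \code{order_filtered},
#'   \code{diagonal_estimate}.
#' @export
hessian_report <- function(sol, backend = NULL, magnitude_threshold = 1,
                           fd_step = 1e-4) {
  if (is.null(backend)) backend <- ppp_backend(sol$spec)
  nh <- numeric_hessian(sol$state, backend, fd_step)
  eigs <- sort(eigen(nh$hessian, symmetric = TRUE, only.values = TRUE)$values) *
    HARTREE_EV
  structure(list(eigenvalues = eigs,
                 order_all = saddle_order(eigs, 0),
                 order_filtered = saddle_order(eigs, magnitude_threshold),
                 diagonal_estimate = diagonal_order_estimate(
                   sol$eps_up, sol$f_up, sol$eps_dn, sol$f_dn)),
            class = "hessian_report")
}

#' @export
print.hessian_report <- function(x, ...) {
  cat("Electronic Hessian analysis\n")
  cat("  negative eigenvalues (order):", x$order_all, "\n")
  cat("  order with |lambda| > 1 eV filter:", x$order_filtered, "\n")
  cat("  diagonal-model estimate:", x$diagonal_estimate, "\n")
  cat("  lowest eigenvalues (eV):",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Energy scan along a single orbital-rotation angle
#'
#' Energies of the state rotated by angle theta in the (i, j) orbital pair
#' of one spin channel, together with the local quadratic quasi-Newton model
#' \eqn{E_0 + g\theta + \tfrac12 d\theta^2} built from the analytic gradient
#' and the diagonal Hessian element at the expansion point.
#'
#' @param state an \code{orbital_state}.
#' @param backend the backend.
#' @param pair integer pair (i, j).
#' @param angles angles in radians.
#' @param spin \code{"up"} or \code{"dn"}.
#' @return data.frame with columns \code{angle}, \code{energy},
#'   \code{model}; attribute \code{gradient} and \code{curvature} carry the
#'   model coefficients.
#' @export
rotation_scan <- function(state, backend, pair, angles, spin = c("up", "dn")) {
  spin <- match.arg(spin)
  i <- pair[1]; j <- pair[2]
  M <- state$M
  energies <- vapply(angles, function(th) {
    K <- matrix(0, M, M); K[i, j] <- th; K[j, i] <- -th
    st <- if (spin == "up") apply_unitary(state, K, NULL)
          else apply_unitary(state, NULL, K)
    backend_evaluate(backend, st)$energy
  }, numeric(1))
  ev <- backend_evaluate(backend, state)
  if (spin == "up") {
    H <- mo_hamiltonian(state$C_up, ev$F_up); f <- state$f_up
  } else {
    H <- mo_hamiltonian(state$C_dn, ev$F_dn); f <- state$f_dn
  }
  g <- 2 * (f[j] - f[i]) * H[i, j]
  d <- 2 * (H[i, i] - H[j, j]) * (f[j] - f[i])
  out <- data.frame(angle = angles, energy = energies,
                    model = ev$energy + g * angles + 0.5 * d * angles^2)
  attr(out, "gradient") <- g
  attr(out, "curvature") <- d
  out
}
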