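# Frozen-orbital constraints and the maximum-overlap occupation controller.

#' Relaxed/frozen orbital partition implied by a set of excitations
#'
#' Freezes every hole and particle orbital of the spin channels carrying an
#' excitation; all pairwise rotations touching a frozen orbital are excluded
#' from the optimization variables.  Channels without excitations relax
#' fully.
#'
#' @param excitations data.frame with columns \code{hole}, \code{particle},
#'   \code{spin} ("up"/"dn").
#' @param M basis size.
#' @param f_up,f_dn occupation vectors of the guess (used to validate that
#'   holes are occupied and particles unoccupied \emph{in the ground state},
#'   i.e. after the swap the hole is empty and the particle filled).
#' @return list with relaxed index sets \code{s_up}, \code{s_dn} and frozen
#'   sets \code{frozen_up}, \code{frozen_dn}.
#' @export
frozen_pair_mask <- function(excitations, M, f_up = NULL, f_dn = NULL) {
  frozen_up <- integer(0); frozen_dn <- integer(0)
  if (!is.null(excitations) && nrow(excitations)) {
    if (any(excitations$hole < 1 | excitations$hole > M |
            excitations$particle < 1 | excitations$particle > M))
      stop("excitation index out of range")
    for (k in seq_len(nrow(excitations))) {
      sp <- excitations$spin[k]
      f <- if (sp == "up") f_up else f_dn
      if (!is.null(f)) {
        # occupations here are those of the nonaufbau guess: hole empty,
        # particle filled after the swap
        if (f[excitations$hole[k]] > 0.5 || f[excitations$particle[k]] < 0.5)
          stop("hole/particle occupation inconsistent with the guess")
      }
      idx <- c(excitations$hole[k], excitations$particle[k])
      if (sp == "up") frozen_up <- union(frozen_up, idx)
      else frozen_dn <- union(frozen_dn, idx)
    }
  }
  list(s_up = setdiff(seq_len(M), frozen_up),
       s_dn = setdiff(seq_len(M), frozen_dn),
       frozen_up = sort(frozen_up), frozen_dn = sort(frozen_dn))
}

#' Create a maximum-overlap reference
#'
#' Captures the occupied columns of the initial-guess orbitals per spin; the
#' reference is kept fixed for the whole run.
#'
#' @param state the initial-guess \code{orbital_state}.
#' @return list with \code{C_occ_up}, \code{C_occ_dn}, \code{N_up},
#'   \code{N_dn}.
#' @export
mom_reference <- function(state) {
  list(C_occ_up = state$C_up[, state$f_up > 0.5, drop = FALSE],
       C_occ_dn = state$C_dn[, state$f_dn > 0.5, drop = FALSE],
       N_up = sum(state$f_up > 0.5), N_dn = sum(state$f_dn > 0.5))
}

#' Overlaps of current orbitals with the reference occupied space
#'
#' \eqn{\Omega_{ri} = (C_{ref,occ}^\dagger S C)_{ri}}.
#'
#' @param C_ref_occ reference occupied columns (M x N_occ).
#' @param S overlap matrix.
#' @param C current coefficient matrix.
#' @return N_occ x M overlap matrix.
#' @export
mom_overlaps <- function(C_ref_occ, S, C) {
  crossprod(C_ref_occ, S %*% C)
}

#' Maximum-overlap weights
#'
#' \eqn{\omega_i = \sum_r |\Omega_{ri}|^2}: the squared projection of each
#' current orbital onto the reference occupied space.  The weights sum to the
#' number of reference occupied orbitals for any unitary C.
#'
#' @param Omega overlap matrix from \code{\link{mom_overlaps}}.
#' @return numeric vector of length M.
#' @export
mom_weights <- function(Omega) {
  colSums(Omega^2)
}

#' Maximum-overlap occupation selection
#'
#' Occupies the \code{N_occ} orbitals of largest weight.  When the decision
#' boundary is a tie (within 1e-12), the current occupation is kept, which
#' avoids oscillation at exactly mixed (45-degree) configurations.
#'
#' @param omega weights from \code{\link{mom_weights}}.
#' @param N_occ number of orbitals to occupy.
#' @param f_current current occupation vector (tie-break reference).
#' @return new 0/1 occupation vector.
#' @export
mom_select <- function(omega, N_occ, f_current) {
  M <- length(omega)
  if (N_occ == 0) return(numeric(M))
  ord <- order(omega, decreasing = TRUE)
  thr <- omega[ord[N_occ]]
  lo <- if (N_occ < M) omega[ord[N_occ + 1]] else -Inf
  if (thr - lo < 1e-12) {
    # boundary tie: candidates straddling the threshold are resolved by the
    # current occupation
    sure <- omega > thr + 1e-12
    tied <- abs(omega - thr) <= 1e-12 | (omega > lo - 1e-12 & omega <= thr + 1e-12)
    tied <- tied & !sure
    f <- numeric(M)
    f[sure] <- 1
    need <- N_occ - sum(sure)
    tie_idx <- which(tied)
    # prefer currently occupied among the tied, then larger weight
    tie_idx <- tie_idx[order(-f_current[tie_idx], -omega[tie_idx])]
    f[tie_idx[seq_len(need)]] <- 1
    return(f)
  }
  f <- numeric(M)
  f[ord[seq_len(N_occ)]] <- 1
  f
}
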