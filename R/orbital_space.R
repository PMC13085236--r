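# Orbital representation and the exponential-unitary machinery.
#
# Orbitals are columns of a coefficient matrix per spin channel; variational
# steps act through C = C0 exp(kappa) with kappa anti-Hermitian.  Only
# rotations between orbitals of different occupation change the energy, so
# the optimization variables are the nonredundant pairs (i < j, f_i != f_j)
# of each spin channel, concatenated up-then-down.

#' Construct an orbital state
#'
#' @param C_up,C_dn coefficient matrices (M x M), columns orthonormal under
#'   the backend overlap.
#' @param f_up,f_dn occupation vectors with entries in {0, 1}.
#' @param n_valence total electron count (used to normalize the residual).
#' @return an object of class \code{orbital_state}; the current and reference
#'   coefficients start out equal.
#' @export
orbital_state <- function(C_up, C_dn, f_up, f_dn, n_valence = sum(f_up) + sum(f_dn)) {
  M <- nrow(C_up)
  stopifnot(ncol(C_up) == M, all(dim(C_dn) == M),
            length(f_up) == M, length(f_dn) == M,
            all(f_up %in% c(0, 1)), all(f_dn %in% c(0, 1)))
  structure(list(C_up = C_up, C_dn = C_dn, C0_up = C_up, C0_dn = C_dn,
                 f_up = f_up, f_dn = f_dn, M = M, n_valence = n_valence),
            class = "orbital_state")
}

#' Nonredundant rotation pairs of one spin channel
#'
#' @param f occupation vector.
#' @param subset optional index set: pairs restricted to lie within it.
#' @param redundant if TRUE include equal-occupation pairs (full
#'   parametrization, used when occupations may change during a run).
#' @return two-column integer matrix of pairs (i < j); zero rows if none.
#' @export
kappa_pairs <- function(f, subset = NULL, redundant = FALSE) {
  M <- length(f)
  idx <- if (is.null(subset)) seq_len(M) else sort(as.integer(subset))
  if (length(idx) < 2) return(matrix(integer(0), 0, 2))
  cmb <- t(utils::combn(idx, 2))
  if (!redundant) cmb <- cmb[f[cmb[, 1]] != f[cmb[, 2]], , drop = FALSE]
  storage.mode(cmb) <- "integer"
  cmb
}

# assemble the antisymmetric matrix implied by pairwise parameters
kappa_matrix <- function(pairs, values, M) {
  K <- matrix(0, M, M)
  if (nrow(pairs)) {
    K[pairs] <- values
    K[pairs[, c(2, 1), drop = FALSE]] <- -values
  }
  K
}

#' Exponential of an anti-Hermitian (real antisymmetric) rotation generator
#'
#' Computed exactly through the Hermitian eigendecomposition of
#' \eqn{i\kappa}; the result is the real orthogonal matrix \eqn{e^\kappa}.
#'
#' @param kappa real antisymmetric M x M matrix.
#' @return orthogonal matrix U with \eqn{U^\dagger U = I}.
#' @export
expm_antihermitian <- function(kappa) {
  if (!all(is.finite(kappa))) stop("kappa has non-finite entries")
  M <- nrow(kappa)
  if (max(abs(kappa + t(kappa))) > 1e-12 * max(1, max(abs(kappa))))
    stop("kappa is not antisymmetric")
  if (max(abs(kappa)) == 0) return(diag(M))
  e <- eigen(1i * kappa, symmetric = TRUE)
  U <- e$vectors %*% (exp(-1i * e$values) * Conj(t(e$vectors)))
  Re(U)
}

#' Apply a unitary orbital rotation
#'
#' Replaces the current coefficients by \eqn{C = C_0 e^\kappa} per spin and
#' re-references (the rotated orbitals become the new reference), so the next
#' gradient is evaluated at \eqn{\kappa = 0}.
#'
#' @param state an \code{orbital_state}.
#' @param kappa_up,kappa_dn antisymmetric generators per spin (either may be
#'   NULL for no rotation in that channel).
#' @return the rotated \code{orbital_state}.
#' @export
apply_unitary <- function(state, kappa_up = NULL, kappa_dn = NULL) {
  if (!is.null(kappa_up)) {
    if (nrow(kappa_up) != state$M) stop("kappa_up dimension mismatch")
    state$C_up <- state$C0_up %*% expm_antihermitian(kappa_up)
  }
  if (!is.null(kappa_dn)) {
    if (nrow(kappa_dn) != state$M) stop("kappa_dn dimension mismatch")
    state$C_dn <- state$C0_dn %*% expm_antihermitian(kappa_dn)
  }
  state$C0_up <- state$C_up
  state$C0_dn <- state$C_dn
  state
}

#' Constrained (frozen-orbital) unitary transformation
#'
#' Rotates only the orbitals in the relaxed set \code{s}:
#' \eqn{C_{\mu i} = \sum_{k \in s} C^0_{\mu k} [e^\kappa]_{ki}} for
#' \eqn{i \in s}, while columns outside \code{s} are carried over
#' bit-identically.  With \code{s} equal to all orbitals this reduces to
#' \code{\link{apply_unitary}}.
#'
#' @param state an \code{orbital_state}.
#' @param kappa_s_up,kappa_s_dn antisymmetric generators over the relaxed
#'   subspaces (dimension = length of the subset), or NULL.
#' @param s_up,s_dn relaxed orbital indices per spin.
#' @return the transformed, re-referenced \code{orbital_state}.
#' @export
constrained_transform <- function(state, kappa_s_up = NULL, kappa_s_dn = NULL,
                                  s_up = seq_len(state$M),
                                  s_dn = seq_len(state$M)) {
  rot <- function(C0, kap, s) {
    if (is.null(kap) || length(s) == 0) return(C0)
    if (nrow(kap) != length(s)) stop("reduced kappa dimension mismatch")
    C <- C0
    C[, s] <- C0[, s, drop = FALSE] %*% expm_antihermitian(kap)
    C
  }
  state$C_up <- rot(state$C0_up, kappa_s_up, s_up)
  state$C_dn <- rot(state$C0_dn, kappa_s_dn, s_dn)
  state$C0_up <- state$C_up
  state$C0_dn <- state$C_dn
  state
}

#' Hamiltonian matrix in the current orbital basis
#'
#' \eqn{H_{ij} = \sum_{\mu\nu} C_{\mu i} H_{\mu\nu} C_{\nu j}} for a real
#' symmetric AO-basis (Fock) matrix.
#'
#' @param C coefficient matrix.
#' @param H_AO symmetric AO-basis matrix.
#' @return symmetric matrix in the orbital basis.
#' @export
mo_hamiltonian <- function(C, H_AO) {
  if (nrow(H_AO) != nrow(C)) stop("dimension mismatch")
  H <- crossprod(C, H_AO %*% C)
  (H + t(H)) / 2
}

#' Reduced Hamiltonian over a relaxed orbital subset
#'
#' The constrained-optimization gradient uses the Hamiltonian restricted to
#' the relaxed orbitals: \eqn{H'_{kl}} for \eqn{k, l \in s}, equal to the
#' corresponding submatrix of the full orbital-basis Hamiltonian.
#'
#' @param C coefficient matrix.
#' @param H_AO symmetric AO matrix.
#' @param s relaxed orbital indices.
#' @return length(s) x length(s) symmetric matrix.
#' @export
reduced_hamiltonian <- function(C, H_AO, s) {
  Cs <- C[, s, drop = FALSE]
  H <- crossprod(Cs, H_AO %*% Cs)
  (H + t(H)) / 2
}

#' Electronic gradient over rotation pairs
#'
#' \eqn{g_{ij} = 2 (f_j - f_i) H_{ij}} evaluated at \eqn{\kappa = 0} in the
#' current orbital basis; zero for equal-occupation pairs.
#'
#' @param H_MO orbital-basis Hamiltonian (full or reduced; indices must match
#'   \code{pairs}).
#' @param f occupation vector on the same index set.
#' @param pairs two-column pair matrix from \code{\link{kappa_pairs}}.
#' @return numeric gradient vector, one element per pair.
#' @export
electronic_gradient <- function(H_MO, f, pairs) {
  if (!nrow(pairs)) return(numeric(0))
  2 * (f[pairs[, 2]] - f[pairs[, 1]]) * H_MO[pairs]
}

#' Diagonal Hessian approximation over rotation pairs
#'
#' \eqn{d_{ij} = 2 (\epsilon_i - \epsilon_j)(f_j - f_i)}, the standard
#' diagonal curvature model used as quasi-Newton preconditioner; negative
#' elements flag directions in which the energy should be maximized.
#'
#' @param eps orbital energies.
#' @param f occupation vector.
#' @param pairs two-column pair matrix.
#' @return numeric vector, one element per pair.
#' @export
diagonal_hessian <- function(eps, f, pairs) {
  if (!nrow(pairs)) return(numeric(0))
  2 * (eps[pairs[, 1]] - eps[pairs[, 2]]) * (f[pairs[, 2]] - f[pairs[, 1]])
}

#' Squared residual of the SCF equations
#'
#' \eqn{r = \frac{1}{N} \sum_\sigma \sum_i f_i \sum_{j: f_j \ne f_i}
#' |H_{ji}|^2}, converted to eV\eqn{^2} per valence electron.  The sum runs
#' over couplings between orbitals of different occupation (the Lagrange
#' multipliers within equal-occupation subspaces cancel the corresponding
#' couplings exactly); it vanishes iff the state is stationary.
#'
#' @param H_up,H_dn orbital-basis Hamiltonians per spin.
#' @param f_up,f_dn occupations per spin.
#' @param n_valence total valence electron count N.
#' @param pairs_up,pairs_dn optional restriction of the coupling pairs (used
#'   during constrained optimization); default all different-occupation pairs.
#' @return scalar residual in eV^2 per valence electron.
#' @export
ks_residual <- function(H_up, H_dn, f_up, f_dn, n_valence,
                        pairs_up = NULL, pairs_dn = NULL) {
  if (n_valence <= 0) stop("n_valence must be positive")
  one <- function(H, f, pairs) {
    if (is.null(pairs)) pairs <- kappa_pairs(f)
    if (!nrow(pairs)) return(0)
    act <- f[pairs[, 1]] != f[pairs[, 2]]
    sum(H[pairs[act, , drop = FALSE]]^2)
  }
  (one(H_up, f_up, pairs_up) + one(H_dn, f_dn, pairs_dn)) *
    HARTREE_EV^2 / n_valence
}

#' Diagonalize the Hamiltonian within equal-occupation subspaces
#'
#' Rotates the orbitals of each spin channel so that the orbital-basis
#' Hamiltonian is diagonal within each block of equally occupied orbitals;
#' such rotations leave the energy invariant.  The resulting diagonal
#' elements are the reported orbital energies.  Column signs are fixed so the
#' largest-magnitude coefficient of each orbital is positive.
#'
#' @param state an \code{orbital_state}.
#' @param backend the backend supplying the Fock matrices.
#' @return list with the rotated \code{state} and orbital energies
#'   \code{eps_up}, \code{eps_dn}.
#' @export
subspace_diagonalize <- function(state, backend) {
  ev <- backend_evaluate(backend, state)
  fix_spin <- function(C, f, F_AO) {
    H <- mo_hamiltonian(C, F_AO)
    for (val in unique(f)) {
      blk <- which(f == val)
      if (length(blk) < 2) next
      e <- eigen(H[blk, blk], symmetric = TRUE)
      C[, blk] <- C[, blk, drop = FALSE] %*% e$vectors
    }
    # sign convention: largest-magnitude component positive
    for (j in seq_len(ncol(C))) {
      k <- which.max(abs(C[, j]))
      if (C[k, j] < 0) C[, j] <- -C[, j]
    }
    list(C = C, eps = diag(mo_hamiltonian(C, F_AO)))
  }
  up <- fix_spin(state$C_up, state$f_up, ev$F_up)
  dn <- fix_spin(state$C_dn, state$f_dn, ev$F_dn)
  state$C_up <- state$C0_up <- up$C
  state$C_dn <- state$C0_dn <- dn$C
  list(state = state, eps_up = up$eps, eps_dn = dn$eps)
}

#' Orthonormality defect of an orbital state
#'
#' @param state an \code{orbital_state}.
#' @param S overlap matrix (identity for the model backend).
#' @return max-norm of \eqn{C^\dagger S C - I} over both spins.
#' @export
orthonormality_error <- function(state, S = diag(state$M)) {
  err <- function(C) max(abs(crossprod(C, S %*% C) - diag(ncol(C))))
  max(err(state$C_up), err(state$C_dn))
}
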