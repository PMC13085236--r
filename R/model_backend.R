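# Pariser-Parr-Pople (PPP) donor-acceptor model backend.
#
# Zero-differential-overlap pi-electron mean field on two site fragments
# separated by a distance R.  Serves as the self-contained test substrate for
# the orbital optimizers: it supplies an AO-basis Fock matrix, total energy,
# overlap (identity; the site basis is orthonormal) and site densities.

#' Hartree to electron-volt conversion factor
#' @export
HARTREE_EV <- 27.211386

#' Define a donor-acceptor PPP dimer
#'
#' Builds the specification of a two-fragment Pariser-Parr-Pople model: each
#' fragment is a chain of sites with nearest-neighbour hopping \code{t_intra},
#' on-site repulsion \code{U_p} and site energy \code{alpha_p}; the fragments
#' are placed along the x axis with centroid separation \code{R} (Bohr) and
#' coupled by an inter-fragment hopping \code{t_DA} between the two facing
#' sites.  Inter-site Coulomb interactions follow the Ohno interpolation
#' \eqn{V_{pq} = 1/\sqrt{R_{pq}^2 + a_{pq}^2}} with
#' \eqn{a_{pq} = 2/(U_p + U_q)}, which has the pure \eqn{1/R} Coulomb tail
#' needed for charge-transfer physics.
#'
#' @param n_donor,n_acceptor number of sites on each fragment.
#' @param R centroid-to-centroid fragment separation (Bohr).
#' @param t_intra nearest-neighbour hopping within a fragment (Ha).
#' @param t_DA hopping between the facing donor and acceptor sites (Ha);
#'   0 gives electronically decoupled fragments.
#' @param U_p on-site repulsion (Ha); scalar or one value per site.
#' @param alpha_donor,alpha_acceptor site energies on each fragment (Ha).
#' @param spacing intra-fragment site spacing (Bohr).
#' @param z_p core charges per site; defaults to 1 per site (neutral,
#'   half-filled system).
#' @param n_up,n_dn electron counts per spin channel; default half filling.
#' @return an object of class \code{ppp_dimer_spec}.
#' @export
ppp_dimer_spec <- function(n_donor = 2L, n_acceptor = 2L, R = 20,
                           t_intra = 0.2, t_DA = 0, U_p = 0.4,
                           alpha_donor = 0, alpha_acceptor = -0.3,
                           spacing = 2.0, z_p = NULL,
                           n_up = NULL, n_dn = NULL) {
  n_donor <- as.integer(n_donor); n_acceptor <- as.integer(n_acceptor)
  if (n_donor < 1L || n_acceptor < 1L) stop("fragments need at least one site")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  M <- n_donor + n_acceptor
  # donor chain ends at x = 0 shifted to put centroids R apart
  xd <- seq_len(n_donor) * spacing
  xa <- seq_len(n_acceptor) * spacing
  xd <- xd - mean(xd)
  xa <- xa - mean(xa) + R
  positions <- cbind(x = c(xd, xa), y = 0, z = 0)
  U_p <- rep_len(U_p, M)
  alpha_p <- c(rep_len(alpha_donor, n_donor), rep_len(alpha_acceptor, n_acceptor))
  if (is.null(z_p)) z_p <- rep(1, M)
  z_p <- rep_len(z_p, M)
  ne <- sum(z_p)
  if (is.null(n_up)) n_up <- ceiling(ne / 2)
  if (is.null(n_dn)) n_dn <- ne - n_up
  stopifnot(n_up + n_dn == ne)
  structure(list(n_donor = n_donor, n_acceptor = n_acceptor, R = R,
                 t_intra = t_intra, t_DA = t_DA, U_p = U_p,
                 alpha_p = alpha_p, spacing = spacing, z_p = z_p,
                 positions = positions, n_up = as.integer(n_up),
                 n_dn = as.integer(n_dn), M = M),
            class = "ppp_dimer_spec")
}

#' @export
print.ppp_dimer_spec <- function(x, ...) {
  cat("PPP donor-acceptor dimer:", x$n_donor, "+", x$n_acceptor, "sites,",
      "R =", x$R, "Bohr\n")
  cat("  t_intra =", x$t_intra, "Ha, t_DA =", x$t_DA,
      "Ha, U =", paste(unique(x$U_p), collapse = "/"), "Ha\n")
  cat("  electrons:", x$n_up, "up,", x$n_dn, "down\n")
  invisible(x)
}

#' Build the mean-field backend for a PPP dimer
#'
#' Assembles the one-electron Hamiltonian
#' \eqn{h_{pq} = \delta_{pq}(\alpha_p - \sum_{r \ne p} V_{pr} z_r) - t_{pq}}
#' and the Ohno Coulomb matrix, and returns a backend object exposing
#' \code{evaluate(state)} (total energy + spin Fock matrices),
#' \code{density(state)} (site populations per spin), the overlap matrix
#' (identity in the orthonormal site basis), positions, core charges and
#' the valence electron count.
#'
#' @param spec a \code{ppp_dimer_spec}.
#' @return an object of class \code{ppp_backend}.
#' @export
ppp_backend <- function(spec) {
  stopifnot(inherits(spec, "ppp_dimer_spec"))
  M <- spec$M
  pos <- spec$positions
  Rpq <- as.matrix(stats::dist(pos))
  a <- outer(spec$U_p, spec$U_p, function(u, v) 2 / (u + v))
  V <- 1 / sqrt(Rpq^2 + a^2)
  diag(V) <- spec$U_p
  # hopping matrix: nearest neighbours within fragments + facing-site coupling
  tmat <- matrix(0, M, M)
  nd <- spec$n_donor
  if (nd > 1) for (p in seq_len(nd - 1)) tmat[p, p + 1] <- tmat[p + 1, p] <- spec$t_intra
  if (spec$n_acceptor > 1) {
    for (p in seq_len(spec$n_acceptor - 1)) {
      i <- nd + p; tmat[i, i + 1] <- tmat[i + 1, i] <- spec$t_intra
    }
  }
  tmat[nd, nd + 1] <- tmat[nd + 1, nd] <- spec$t_DA
  Voff <- V; diag(Voff) <- 0
  h <- diag(spec$alpha_p - as.vector(Voff %*% spec$z_p), M) - tmat
  E_core <- 0.5 * sum(Voff * outer(spec$z_p, spec$z_p))
  backend <- list(spec = spec, h = h, V = V, S = diag(M), M = M,
                  positions = pos, z = spec$z_p,
                  n_valence = spec$n_up + spec$n_dn, E_core = E_core)
  class(backend) <- "ppp_backend"
  backend
}

# spin density matrices P_sigma = C_occ C_occ^T from an orbital state
density_matrices <- function(backend, state) {
  P <- function(C, f) {
    occ <- which(f > 0.5)
    if (length(occ) == 0) return(matrix(0, backend$M, backend$M))
    Co <- C[, occ, drop = FALSE]
    Co %*% t(Co)
  }
  list(up = P(state$C_up, state$f_up), dn = P(state$C_dn, state$f_dn))
}

#' Mean-field energy and Fock matrices from spin density matrices
#'
#' Computes the unrestricted PPP mean-field energy and the spin Fock matrices
#' \eqn{F_\sigma = h + J - K_\sigma} with the ZDO Coulomb term
#' \eqn{J_{pq} = \delta_{pq} \sum_r V_{pr} n_r} and exchange
#' \eqn{K_{\sigma,pq} = V_{pq} P_{\sigma,pq}};
#' \eqn{E = \tfrac12\sum_\sigma \mathrm{Tr}[P_\sigma(h + F_\sigma)] + E_{core}}.
#'
#' @param backend a \code{ppp_backend}.
#' @param P_up,P_dn spin density matrices in the site basis.
#' @return list with \code{energy} (Ha), \code{F_up}, \code{F_dn}.
#' @export
fock_energy <- function(backend, P_up, P_dn) {
  if (max(abs(P_up - t(P_up))) > 1e-8 || max(abs(P_dn - t(P_dn))) > 1e-8)
    stop("density matrices must be symmetric")
  n_tot <- diag(P_up) + diag(P_dn)
  J <- diag(as.vector(backend$V %*% n_tot), backend$M)
  K_up <- backend$V * P_up
  K_dn <- backend$V * P_dn
  F_up <- backend$h + J - K_up
  F_dn <- backend$h + J - K_dn
  E <- 0.5 * (sum(P_up * (backend$h + F_up)) + sum(P_dn * (backend$h + F_dn))) +
    backend$E_core
  list(energy = E, F_up = F_up, F_dn = F_dn)
}

#' Evaluate a backend at an orbital state
#'
#' @param backend a \code{ppp_backend}.
#' @param state an \code{orbital_state}.
#' @return list with \code{energy}, \code{F_up}, \code{F_dn}.
#' @export
backend_evaluate <- function(backend, state) {
  P <- density_matrices(backend, state)
  fock_energy(backend, P$up, P$dn)
}

#' Site densities of an orbital state
#'
#' @param backend a \code{ppp_backend}.
#' @param state an \code{orbital_state}.
#' @return list of \code{density_sample} objects \code{up}, \code{dn},
#'   \code{total} (points = site positions, weights = populations).
#' @export
backend_density <- function(backend, state) {
  P <- density_matrices(backend, state)
  up <- density_sample(backend$positions, diag(P$up))
  dn <- density_sample(backend$positions, diag(P$dn))
  tot <- density_sample(backend$positions, diag(P$up) + diag(P$dn))
  list(up = up, dn = dn, total = tot)
}

#' Fixed-point SCF solver (oracle for the direct minimizer)
#'
#' Conventional repeated Fock diagonalization with linear density mixing.
#' Occupations are aufbau per spin unless explicit occupation vectors are
#' supplied.  Used as an independent route to the ground-state energy.
#'
#' @param backend a \code{ppp_backend}.
#' @param f_up,f_dn optional 0/1 occupation vectors; default aufbau.
#' @param damping fraction of the new density mixed in each cycle.
#' @param tol convergence threshold on the energy change (Ha).
#' @param max_iter iteration cap.
#' @return list with \code{energy}, \code{C_up}, \code{C_dn}, \code{eps_up},
#'   \code{eps_dn}, \code{f_up}, \code{f_dn}, \code{P_up}, \code{P_dn},
#'   \code{iterations}, \code{converged}.
#' @export
scf_fixed_point <- function(backend, f_up = NULL, f_dn = NULL,
                            damping = 0.3, tol = 1e-12, max_iter = 2000L) {
  M <- backend$M
  spec <- backend$spec
  occ_vec <- function(eps, n) {
    f <- numeric(M); f[order(eps)[seq_len(n)]] <- 1; f
  }
  aufbau_up <- is.null(f_up); aufbau_dn <- is.null(f_dn)
  e0 <- eigen(backend$h, symmetric = TRUE)
  C_up <- C_dn <- e0$vectors
  if (aufbau_up) f_up <- occ_vec(e0$values, spec$n_up)
  if (aufbau_dn) f_dn <- occ_vec(e0$values, spec$n_dn)
  Pmat <- function(C, f) {
    occ <- which(f > 0.5)
    if (!length(occ)) return(matrix(0, M, M))
    C[, occ, drop = FALSE] %*% t(C[, occ, drop = FALSE])
  }
  P_up <- Pmat(C_up, f_up); P_dn <- Pmat(C_dn, f_dn)
  E_old <- Inf; converged <- FALSE; it <- 0L
  eps_up <- eps_dn <- NULL
  for (it in seq_len(max_iter)) {
    fe <- fock_energy(backend, P_up, P_dn)
    eu <- eigen(fe$F_up, symmetric = TRUE)
    ed <- eigen(fe$F_dn, symmetric = TRUE)
    C_up <- eu$vectors; C_dn <- ed$vectors
    eps_up <- eu$values; eps_dn <- ed$values
    if (aufbau_up) f_up <- occ_vec(eps_up, spec$n_up)
    if (aufbau_dn) f_dn <- occ_vec(eps_dn, spec$n_dn)
    P_up_new <- Pmat(C_up, f_up); P_dn_new <- Pmat(C_dn, f_dn)
    P_up <- (1 - damping) * P_up + damping * P_up_new
    P_dn <- (1 - damping) * P_dn + damping * P_dn_new
    if (abs(fe$energy - E_old) < tol) { converged <- TRUE; break }
    E_old <- fe$energy
  }
  # final energy from the idempotent (undamped) density
  P_up <- Pmat(C_up, f_up); P_dn <- Pmat(C_dn, f_dn)
  fe <- fock_energy(backend, P_up, P_dn)
  list(energy = fe$energy, C_up = C_up, C_dn = C_dn,
       eps_up = eps_up, eps_dn = eps_dn, f_up = f_up, f_dn = f_dn,
       P_up = P_up, P_dn = P_dn, iterations = it, converged = converged)
}

#' Generate a seeded donor-acceptor test fixture
#'
#' Produces a \code{ppp_dimer_spec} of one of two kinds.  \code{"decoupled"}:
#' inter-fragment hopping is zero and the fragments are well gapped, so the
#' charge-transfer excited state is a clean saddle point.  \code{"collapse"}:
#' a spin-polarized dimer (one up electron per fragment, no down electrons)
#' whose separation, site energies and inter-fragment hopping are tuned by a
#' deterministic dense search over rotation scans of the occupied/hole
#' orbital pair, so that the energy along that rotation has a spurious
#' mixed-orbital minimum near 45 degrees below the charge-transfer guess and
#' the diagonal curvature along the pair flips sign across the constrained
#' phase -- the charge-delocalization trap that defeats maximum-overlap
#' occupation control.  Spin polarization matters: with paired electrons the
#' exchange-free opposite-spin channel screens the vacated donor level back
#' up, and the trap cannot form in an exact-exchange model.
#'
#' @param seed integer seed; the same seed always yields the same spec.
#' @param kind \code{"decoupled"} or \code{"collapse"}.
#' @return a \code{ppp_dimer_spec}.
#' @export
generate_fixture <- function(seed, kind = c("decoupled", "collapse")) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  t_intra <- stats::runif(1, 0.15, 0.25)
  U <- stats::runif(1, 0.35, 0.5)
  dalpha <- stats::runif(1, 0.25, 0.4)
  if (kind == "decoupled") {
    R <- stats::runif(1, 15, 30)
    return(ppp_dimer_spec(R = R, t_intra = t_intra, t_DA = 0, U_p = U,
                          alpha_donor = 0, alpha_acceptor = -dalpha))
  }
  # Spin-polarized collapse family.  The base point was located by a dense
  # offline parameter search; the seeded jitter below stays inside the
  # region where every sampled point exhibits the trap, and each candidate
  # is still verified by a dense rotation scan before being accepted.
  for (attempt in seq_len(40L)) {
    spec <- ppp_dimer_spec(
      R = stats::runif(1, 23.4, 24.0),
      t_intra = 0.2,
      t_DA = 0.10 * (1 + stats::runif(1, -0.03, 0.03)),
      U_p = 0.5,
      alpha_donor = 0,
      alpha_acceptor = c(-0.08 * (1 + stats::runif(1, -0.05, 0.05)),
                         -0.18 * (1 + stats::runif(1, -0.05, 0.05))),
      spacing = 1.5, z_p = 0.5, n_up = 2L, n_dn = 0L)
    if (isTRUE(collapse_scan_ok(spec))) return(spec)
  }
  stop("collapse fixture search failed for seed ", seed,
       ": no candidate in the scanned family produces the 45-degree ",
       "delocalization trap")
}

# Dense rotation-scan check used by the collapse fixture search: at the
# nonaufbau guess, the energy along the occupied/hole mixing angle must
# have an interior minimum near 45 deg strictly below the charge-transfer
# guess, and the diagonal-Hessian curvature along that pair must be
# positive at the guess and negative after constrained relaxation (orbitals
# tracked by overlap, since constrained relaxation reorders them).
# "Below the target saddle" is verified literally: the freeze-and-release
# run must hold a charge-transfer saddle above the scan minimum, while the
# maximum-overlap baseline must fall into the trap (strictly lower energy,
# strictly smaller charge-transfer distance).
collapse_scan_ok <- function(spec, depth_min = 1e-3, band_deg = 17) {
  res <- try({
    backend <- ppp_backend(spec)
    gs <- ground_state(backend)
    exc <- homo_lumo_excitation(gs)
    guess <- initial_guess(gs, exc)
    hole <- exc$hole[1]
    pair <- mixing_pair(guess$state, gs$eps_up, hole)
    if (is.null(pair)) return(FALSE)
    partner <- pair[pair != hole]
    th <- seq(-20, 80, by = 2) * pi / 180
    sc <- rotation_scan(guess$state, backend, c(pair[1], pair[2]), th,
                        spin = "up")
    i0 <- which.min(abs(th))
    imin <- which.min(sc$energy)
    ok_shape <- imin > 1 && imin < length(th) &&
      abs(th[imin] - pi / 4) < band_deg * pi / 180 &&
      sc$energy[i0] - sc$energy[imin] > depth_min
    if (!ok_shape) return(FALSE)
    # curvature sign flip across constrained relaxation
    d_guess <- 2 * (gs$eps_up[hole] - gs$eps_up[partner])
    con <- run_constrained(guess, backend)
    ovh <- abs(crossprod(con$state$C_up, guess$state$C_up[, hole]))
    ovp <- abs(crossprod(con$state$C_up, guess$state$C_up[, partner]))
    virt <- which(con$state$f_up < 0.5)
    occ <- which(con$state$f_up > 0.5)
    d_con <- 2 * (con$eps_up[virt[which.max(ovh[virt])]] -
                    con$eps_up[occ[which.max(ovp[occ])]])
    if (!(d_guess > 0 && d_con < 0)) return(FALSE)
    fr <- frdo(backend)
    dm <- do_mom(backend)
    fr$converged && dm$converged &&
      fr$diagnostics$q_CT > 0.5 &&
      min(sc$energy) < fr$energy &&
      dm$energy < fr$energy - 1e-5 &&
      dm$diagnostics$d_CT < fr$diagnostics$d_CT - 1e-3
  }, silent = TRUE)
  if (inherits(res, "try-error")) FALSE else isTRUE(res)
}

# Highest occupied orbital strictly below the hole in the hole's spin channel
# (the partner of the delocalizing 2x2 rotation).
mixing_pair <- function(state, eps, hole) {
  occ_below <- which(state$f_up > 0.5 & eps < eps[hole] - 1e-12)
  occ_below <- setdiff(occ_below, hole)
  if (!length(occ_below)) return(NULL)
  i <- occ_below[which.max(eps[occ_below])]
  sort(c(i, hole))
}

#' Rebuild a dimer spec at a different fragment separation
#'
#' @param spec a \code{ppp_dimer_spec}.
#' @param R new centroid separation (Bohr).
#' @return a \code{ppp_dimer_spec} identical except for the separation.
#' @export
spec_at_separation <- function(spec, R) {
  ppp_dimer_spec(n_donor = spec$n_donor, n_acceptor = spec$n_acceptor,
                 R = R, t_intra = spec$t_intra, t_DA = spec$t_DA,
                 U_p = spec$U_p,
                 alpha_donor = spec$alpha_p[seq_len(spec$n_donor)],
                 alpha_acceptor = spec$alpha_p[spec$n_donor + seq_len(spec$n_acceptor)],
                 spacing = spec$spacing, z_p = spec$z_p,
                 n_up = spec$n_up, n_dn = spec$n_dn)
}

#' HOMO -> LUMO charge-transfer excitation of a ground-state solution
#'
#' Convenience constructor for the single-excitation list: promotes the
#' up-spin electron from the highest occupied to the lowest unoccupied
#' ground-state orbital.
#'
#' @param ground a \code{frdo_solution} from \code{\link{ground_state}}.
#' @return a data.frame with columns \code{hole}, \code{particle}, \code{spin}.
#' @export
homo_lumo_excitation <- function(ground) {
  f <- ground$state$f_up
  eps <- ground$eps_up
  homo <- which(f > 0.5)[which.max(eps[f > 0.5])]
  lumo <- which(f < 0.5)[which.min(eps[f < 0.5])]
  data.frame(hole = homo, particle = lumo, spin = "up",
             stringsAsFactors = FALSE)
}
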