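# End-to-end orbital optimizers.
#
# ground_state(): direct minimization of the aufbau determinant (L-BFGS).
# frdo():         freeze-and-release direct optimization -- constrained
#                 minimization with the hole/particle orbitals frozen,
#                 followed by an unconstrained L-SR1 saddle search.
# do_mom():       direct optimization with maximum-overlap occupation
#                 control, the baseline that is prone to variational
#                 collapse for charge-transfer states.

#' Optimizer run settings
#'
#' @param tol_full convergence threshold on the squared SCF residual
#'   (eV^2 per valence electron) for full optimizations.
#' @param tol_constrained looser threshold used by the constrained step.
#' @param max_iter iteration cap per phase.
#' @param max_step_constrained L-BFGS max-norm step cap (constrained phase).
#' @param max_step_released L-SR1 step cap after releasing the constraints.
#' @param max_step_domom L-SR1 step cap for the MOM-controlled baseline.
#' @param memory quasi-Newton memory length.
#' @param floor magnitude floor of the diagonal preconditioner (Ha).
#' @return a list of class \code{run_settings}.
#' @export
run_settings <- function(tol_full = 4e-8, tol_constrained = 4e-3,
                         max_iter = 333L, max_step_constrained = 0.2,
                         max_step_released = 0.1, max_step_domom = 0.2,
                         memory = 20L, floor = 1e-3) {
  s <- list(tol_full = tol_full, tol_constrained = tol_constrained,
            max_iter = as.integer(max_iter),
            max_step_constrained = max_step_constrained,
            max_step_released = max_step_released,
            max_step_domom = max_step_domom,
            memory = as.integer(memory), floor = floor)
  if (any(unlist(s) <= 0)) stop("all settings must be positive")
  if (s$tol_constrained < s$tol_full)
    stop("tol_constrained must not be tighter than tol_full")
  class(s) <- "run_settings"
  s
}

# One quasi-Newton optimization phase over a fixed variable space.
#
# algorithm "lbfgs" minimizes (positive-clamped preconditioner), "lsr1"
# searches for the stationary point matching the sign structure of the
# preconditioner.  When mom_ref is given, occupations are reassigned by
# maximum overlap after every step and the variable space is the full pair
# set (so it survives occupation changes).
optimize_phase <- function(backend, state, algorithm, max_step, tol, max_iter,
                           eps_up, eps_dn, s_up = NULL, s_dn = NULL,
                           mom_ref = NULL, memory = 20L, floor = 1e-3,
                           phase_name = algorithm) {
  M <- state$M
  if (is.null(s_up)) s_up <- seq_len(M)
  if (is.null(s_dn)) s_dn <- seq_len(M)
  redundant <- !is.null(mom_ref)
  pairs_up <- kappa_pairs(state$f_up, subset = s_up, redundant = redundant)
  pairs_dn <- kappa_pairs(state$f_dn, subset = s_dn, redundant = redundant)
  n_up <- nrow(pairs_up)
  d0 <- c(diagonal_hessian(eps_up, state$f_up, pairs_up),
          diagonal_hessian(eps_dn, state$f_dn, pairs_dn))
  precond <- make_preconditioner(d0, floor)
  qn <- qn_state(precond, max_step, memory)
  step_fun <- if (algorithm == "lbfgs") lbfgs_step else lsr1_step
  g_prev <- NULL; s_prev <- NULL
  trace <- vector("list", max_iter)
  converged <- FALSE; steps <- 0L
  energy <- NA_real_; resid <- NA_real_
  for (it in seq_len(max_iter)) {
    ev <- backend_evaluate(backend, state)
    H_up <- mo_hamiltonian(state$C_up, ev$F_up)
    H_dn <- mo_hamiltonian(state$C_dn, ev$F_dn)
    g <- c(electronic_gradient(H_up, state$f_up, pairs_up),
           electronic_gradient(H_dn, state$f_dn, pairs_dn))
    rp_up <- if (redundant) NULL else pairs_up
    rp_dn <- if (redundant) NULL else pairs_dn
    resid <- ks_residual(H_up, H_dn, state$f_up, state$f_dn,
                         state$n_valence, rp_up, rp_dn)
    energy <- ev$energy
    trace[[it]] <- c(iteration = it, energy = energy, residual = resid,
                     step_max = if (is.null(s_prev)) 0 else max(abs(s_prev)))
    if (resid <= tol) { converged <- TRUE; break }
    if (!is.null(g_prev)) qn <- qn_update(qn, s_prev, g - g_prev)
    step <- step_fun(qn, g)
    g_prev <- g; s_prev <- step
    steps <- steps + 1L
    kap_up <- if (n_up) kappa_matrix(
      cbind(match(pairs_up[, 1], s_up), match(pairs_up[, 2], s_up)),
      step[seq_len(n_up)], length(s_up)) else NULL
    kap_dn <- if (nrow(pairs_dn)) kappa_matrix(
      cbind(match(pairs_dn[, 1], s_dn), match(pairs_dn[, 2], s_dn)),
      step[n_up + seq_len(nrow(pairs_dn))], length(s_dn)) else NULL
    state <- constrained_transform(state, kap_up, kap_dn, s_up, s_dn)
    if (redundant) {
      Om_up <- mom_overlaps(mom_ref$C_occ_up, backend$S, state$C_up)
      Om_dn <- mom_overlaps(mom_ref$C_occ_dn, backend$S, state$C_dn)
      state$f_up <- mom_select(mom_weights(Om_up), mom_ref$N_up, state$f_up)
      state$f_dn <- mom_select(mom_weights(Om_dn), mom_ref$N_dn, state$f_dn)
    }
  }
  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)]))
  trace$phase <- phase_name
  list(state = state, converged = converged, iterations = steps,
       energy = energy, residual = resid, trace = trace)
}

new_frdo_solution <- function(method, backend, phase, eps, ground = NULL,
                              iterations = NULL, excitations = NULL,
                              settings = NULL, extra_trace = NULL) {
  trace <- if (is.null(extra_trace)) phase$trace else
    rbind(extra_trace, phase$trace)
  sol <- list(method = method, energy = phase$energy,
              residual = phase$residual, converged = phase$converged,
              iterations = iterations %||% list(total = phase$iterations),
              state = phase$state, eps_up = eps$eps_up, eps_dn = eps$eps_dn,
              f_up = phase$state$f_up, f_dn = phase$state$f_dn,
              trace = trace, excitations = excitations,
              settings = settings, spec = backend$spec,
              ground_energy = if (is.null(ground)) NULL else ground$energy,
              excitation_eV = if (is.null(ground)) NULL else
                (phase$energy - ground$energy) * HARTREE_EV,
              diagnostics = NULL)
  class(sol) <- "frdo_solution"
  sol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-state direct minimization
#'
#' Minimizes the mean-field energy over orbital rotations with aufbau
#' occupations using preconditioned L-BFGS, starting from the eigenvectors
#' of the one-electron Hamiltonian.  If the converged orbital energies are
#' not aufbau-ordered, occupations are reassigned and the minimization
#' repeated.
#'
#' @param backend a \code{ppp_backend} (or a \code{ppp_dimer_spec}).
#' @param settings a \code{\link{run_settings}} object.
#' @return a \code{frdo_solution} with \code{method = "ground"}.
#' @export
ground_state <- function(backend, settings = run_settings()) {
  if (inherits(backend, "ppp_dimer_spec")) backend <- ppp_backend(backend)
  M <- backend$M
  e0 <- eigen(backend$h, symmetric = TRUE)
  occ_vec <- function(eps, n) { f <- numeric(M); f[order(eps)[seq_len(n)]] <- 1; f }
  f_up <- occ_vec(e0$values, backend$spec$n_up)
  f_dn <- occ_vec(e0$values, backend$spec$n_dn)
  state <- orbital_state(e0$vectors, e0$vectors, f_up, f_dn)
  phase <- NULL; sd <- NULL
  for (round in 1:6) {
    sd <- subspace_diagonalize(state, backend)
    phase <- optimize_phase(backend, sd$state, "lbfgs",
                            settings$max_step_constrained,
                            settings$tol_full, settings$max_iter,
                            sd$eps_up, sd$eps_dn,
                            memory = settings$memory, floor = settings$floor,
                            phase_name = "ground")
    sd <- subspace_diagonalize(phase$state, backend)
    # enforce aufbau: reoccupy by orbital energy and repeat if changed
    f_up_new <- occ_vec(sd$eps_up, backend$spec$n_up)
    f_dn_new <- occ_vec(sd$eps_dn, backend$spec$n_dn)
    if (identical(f_up_new, sd$state$f_up) &&
        identical(f_dn_new, sd$state$f_dn)) break
    sd$state$f_up <- f_up_new
    sd$state$f_dn <- f_dn_new
    state <- sd$state
  }
  phase$state <- sd$state
  sol <- new_frdo_solution("ground", backend, phase, sd,
                           iterations = list(total = phase$iterations),
                           settings = settings)
  sol$ground_energy <- sol$energy
  sol$excitation_eV <- 0
  sol
}

#' Build the nonaufbau initial guess for an excited-state run
#'
#' Takes the converged ground-state orbitals and swaps the occupation of
#' each (hole, particle) pair in its spin channel -- the usual 90-degree
#' rotation between the orbitals of the excitation.  The coefficients are
#' unchanged; the maximum-overlap reference is captured here.
#'
#' @param ground a \code{frdo_solution} from \code{\link{ground_state}}.
#' @param excitations data.frame with columns \code{hole}, \code{particle},
#'   \code{spin}.
#' @return an object of class \code{frdo_guess}.
#' @export
initial_guess <- function(ground, excitations) {
  stopifnot(inherits(ground, "frdo_solution"), ground$method == "ground")
  state <- ground$state
  for (k in seq_len(nrow(excitations))) {
    sp <- excitations$spin[k]
    h <- excitations$hole[k]; p <- excitations$particle[k]
    f <- if (sp == "up") state$f_up else state$f_dn
    if (h < 1 || p < 1 || h > state$M || p > state$M)
      stop("excitation index out of range")
    if (f[h] < 0.5) stop("hole orbital ", h, " is not occupied")
    if (f[p] > 0.5) stop("particle orbital ", p, " is not virtual")
    f[h] <- 0; f[p] <- 1
    if (sp == "up") state$f_up <- f else state$f_dn <- f
  }
  structure(list(state = state, excitations = excitations,
                 mom_ref = mom_reference(state),
                 eps_up = ground$eps_up, eps_dn = ground$eps_dn,
                 ground_energy = ground$energy, ground = ground),
            class = "frdo_guess")
}

#' Constrained optimization with frozen hole/particle orbitals
#'
#' L-BFGS minimization over rotations among the relaxed orbitals only, to
#' the looser constrained tolerance.  Frozen columns are carried through
#' bit-identically.  A subspace diagonalization afterwards refreshes the
#' orbital energies that seed the released phase's preconditioner.
#'
#' @param guess an \code{frdo_guess}.
#' @param backend the backend.
#' @param settings a \code{\link{run_settings}}.
#' @return list with the partially relaxed \code{state}, refreshed
#'   \code{eps_up}/\code{eps_dn}, \code{iterations}, \code{trace},
#'   \code{converged} and the frozen partition \code{fs}.
#' @export
run_constrained <- function(guess, backend, settings = run_settings()) {
  stopifnot(inherits(guess, "frdo_guess"))
  state <- guess$state
  fs <- frozen_pair_mask(guess$excitations, state$M, state$f_up, state$f_dn)
  phase <- optimize_phase(backend, state, "lbfgs",
                          settings$max_step_constrained,
                          settings$tol_constrained, settings$max_iter,
                          guess$eps_up, guess$eps_dn,
                          s_up = fs$s_up, s_dn = fs$s_dn,
                          memory = settings$memory, floor = settings$floor,
                          phase_name = "constrained")
  sd <- subspace_diagonalize(phase$state, backend)
  list(state = sd$state, eps_up = sd$eps_up, eps_dn = sd$eps_dn,
       iterations = phase$iterations, trace = phase$trace,
       converged = phase$converged, fs = fs, energy = phase$energy,
       residual = phase$residual, guess = guess)
}

#' Released (unconstrained) saddle-point search
#'
#' L-SR1 search over all nonredundant rotation pairs, seeded with the signed
#' preconditioner built from the refreshed orbital energies of the
#' constrained solution; negative preconditioner elements drive the uphill
#' steps toward the target saddle point.
#'
#' @param con result of \code{\link{run_constrained}}.
#' @param backend the backend.
#' @param settings a \code{\link{run_settings}}.
#' @return a \code{frdo_solution} with \code{method = "frdo"}.
#' @export
run_released <- function(con, backend, settings = run_settings()) {
  phase <- optimize_phase(backend, con$state, "lsr1",
                          settings$max_step_released,
                          settings$tol_full, settings$max_iter,
                          con$eps_up, con$eps_dn,
                          memory = settings$memory, floor = settings$floor,
                          phase_name = "released")
  sd <- subspace_diagonalize(phase$state, backend)
  phase$state <- sd$state
  sol <- new_frdo_solution("frdo", backend, phase, sd,
                           ground = con$guess$ground,
                           iterations = list(constrained = con$iterations,
                                             released = phase$iterations,
                                             total = con$iterations + phase$iterations),
                           excitations = con$guess$excitations,
                           settings = settings, extra_trace = con$trace)
  sol$diagnostics <- solution_diagnostics(sol, backend, con$guess$ground)
  sol
}

#' Freeze-and-release direct optimization of an excited state
#'
#' The main fitting function: converges the ground state, builds the
#' nonaufbau guess for the requested excitation, minimizes with the hole and
#' particle orbitals frozen, then releases the constraints and converges on
#' the target saddle point with L-SR1.  With \code{method = "domom"} the
#' constrained step is skipped and occupations are controlled by maximum
#' overlap instead (the collapse-prone baseline).
#'
#' @param x a \code{ppp_backend}, a \code{ppp_dimer_spec}, or a config list
#'   from \code{\link{parse_config}}.
#' @param excitations data.frame(hole, particle, spin); default the up-spin
#'   HOMO -> LUMO charge-transfer excitation.
#' @param settings a \code{\link{run_settings}}.
#' @param method \code{"frdo"} (default) or \code{"domom"}.
#' @param ground optional precomputed ground-state solution (reused across
#'   runs on the same backend).
#' @return a \code{frdo_solution}.
#' @examples
#' spec <- ppp_dimer_spec(R = 20)
#' fit <- frdo(spec)
#' fit
#' @export
frdo <- function(x, excitations = NULL, settings = run_settings(),
                 method = c("frdo", "domom"), ground = NULL) {
  method <- match.arg(method)
  if (is.list(x) && !is.null(x$method) && !inherits(x, "ppp_dimer_spec"))
    return(run_config(x))
  backend <- if (inherits(x, "ppp_dimer_spec")) ppp_backend(x) else x
  stopifnot(inherits(backend, "ppp_backend"))
  if (is.null(ground)) ground <- ground_state(backend, settings)
  if (is.null(excitations)) excitations <- homo_lumo_excitation(ground)
  guess <- initial_guess(ground, excitations)
  if (method == "domom") return(do_mom_run(guess, backend, settings))
  con <- run_constrained(guess, backend, settings)
  run_released(con, backend, settings)
}

#' Direct optimization with maximum-overlap occupation control
#'
#' L-SR1 from the nonaufbau guess, with occupations reassigned every
#' iteration to the orbitals of largest projection onto the guess occupied
#' space, and the preconditioner built from the ground-state orbital
#' energies.
#'
#' @inheritParams frdo
#' @return a \code{frdo_solution} with \code{method = "domom"}.
#' @export
do_mom <- function(x, excitations = NULL, settings = run_settings(),
                   ground = NULL) {
  frdo(x, excitations, settings, method = "domom", ground = ground)
}

do_mom_run <- function(guess, backend, settings) {
  phase <- optimize_phase(backend, guess$state, "lsr1",
                          settings$max_step_domom,
                          settings$tol_full, settings$max_iter,
                          guess$eps_up, guess$eps_dn,
                          mom_ref = guess$mom_ref,
                          memory = settings$memory, floor = settings$floor,
                          phase_name = "domom")
  sd <- subspace_diagonalize(phase$state, backend)
  phase$state <- sd$state
  sol <- new_frdo_solution("domom", backend, phase, sd,
                           ground = guess$ground,
                           iterations = list(total = phase$iterations),
                           excitations = guess$excitations,
                           settings = settings)
  sol$diagnostics <- solution_diagnostics(sol, backend, guess$ground)
  sol
}

# post-convergence diagnostics attached to every excited-state solution
solution_diagnostics <- function(sol, backend, ground) {
  dens_e <- backend_density(backend, sol$state)
  dens_g <- backend_density(backend, ground$state)
  drho <- density_sample(backend$positions,
                         dens_e$total$weights - dens_g$total$weights)
  ct <- tryCatch(ct_distance(drho), error = function(e) list(d_CT = NA, q_CT = NA))
  list(d_CT = ct$d_CT, q_CT = ct$q_CT,
       spin_contamination = spin_contamination(dens_e$up, dens_e$dn),
       dipole = dipole_moment(dens_e$total, backend$z, backend$positions),
       dipole_ground = dipole_moment(dens_g$total, backend$z, backend$positions))
}

#' Excitation-energy scan over fragment separation
#'
#' Runs the full freeze-and-release optimization for the donor HOMO ->
#' acceptor LUMO excitation at each separation in \code{R_grid}, holding all
#' other model parameters fixed, and tabulates ground and excited energies
#' and the charge-transfer diagnostics.  The unrelaxed (frozen-orbital)
#' excitation energy of the bare occupation-swapped guess is included for
#' comparison.
#'
#' @param spec_template a \code{ppp_dimer_spec}; its \code{R} is replaced.
#' @param R_grid separations (Bohr).
#' @param settings a \code{\link{run_settings}}.
#' @return data.frame with columns R, E_ground, E_CT, E_exc_eV,
#'   E_exc_frozen_eV, d_CT, q_CT, converged.
#' @export
dissociation_scan <- function(spec_template, R_grid = c(10, 15, 20, 25, 30),
                              settings = run_settings()) {
  rows <- lapply(R_grid, function(R) {
    spec <- spec_at_separation(spec_template, R)
    backend <- ppp_backend(spec)
    gs <- ground_state(backend, settings)
    exc <- homo_lumo_excitation(gs)
    guess <- initial_guess(gs, exc)
    E_guess <- backend_evaluate(backend, guess$state)$energy
    fit <- frdo(backend, exc, settings, ground = gs)
    data.frame(R = R, E_ground = gs$energy, E_CT = fit$energy,
               E_exc_eV = fit$excitation_eV,
               E_exc_frozen_eV = (E_guess - gs$energy) * HARTREE_EV,
               d_CT = fit$diagnostics$d_CT, q_CT = fit$diagnostics$q_CT,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
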