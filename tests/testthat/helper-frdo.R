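# Shared test helpers: seeded random model instances and matrix utilities.

# a random small PPP dimer spec (M <= 8), half-filled and neutral
random_spec <- function(seed) {
  set.seed(seed)
  nd <- sample(2:4, 1)
  na <- sample(2:4, 1)
  ppp_dimer_spec(n_donor = nd, n_acceptor = na,
                 R = runif(1, 10, 25),
                 t_intra = runif(1, 0.1, 0.3),
                 t_DA = runif(1, 0, 0.08),
                 U_p = runif(nd + na, 0.3, 0.6),
                 alpha_donor = runif(1, -0.1, 0.1),
                 alpha_acceptor = runif(1, -0.4, -0.2),
                 spacing = runif(1, 1.5, 2.5))
}

random_backend <- function(seed) ppp_backend(random_spec(seed))

# a random antisymmetric M x M generator
random_kappa <- function(M, scale = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(M * M, sd = scale), M, M)
  A - t(A)
}

# a random orthogonal matrix (QR of a Gaussian matrix, det sign unfixed)
random_orthogonal <- function(M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(M * M), M, M)))
}

# random orbital state for a backend: rotated eigenvectors of h
random_state <- function(backend, seed = 1, scale = 0.2) {
  set.seed(seed)
  M <- backend$M
  C <- eigen(backend$h, symmetric = TRUE)$vectors
  U1 <- expm_antihermitian(random_kappa(M, scale))
  U2 <- expm_antihermitian(random_kappa(M, scale))
  occ <- function(n) { f <- numeric(M); if (n > 0) f[seq_len(n)] <- 1; f }
  orbital_state(C %*% U1, C %*% U2,
                occ(backend$spec$n_up), occ(backend$spec$n_dn))
}

# total energy as a function of a full kappa step at a state (both spins)
energy_at_kappa <- function(backend, state, pairs_up, pairs_dn, x) {
  n_up <- nrow(pairs_up)
  ku <- frdo:::kappa_matrix(pairs_up, x[seq_len(n_up)], state$M)
  kd <- frdo:::kappa_matrix(pairs_dn, x[n_up + seq_len(nrow(pairs_dn))],
                            state$M)
  backend_evaluate(backend, apply_unitary(state, ku, kd))$energy
}

# analytic concatenated gradient at a state
analytic_gradient <- function(backend, state, pairs_up, pairs_dn) {
  ev <- backend_evaluate(backend, state)
  c(electronic_gradient(mo_hamiltonian(state$C_up, ev$F_up), state$f_up, pairs_up),
    electronic_gradient(mo_hamiltonian(state$C_dn, ev$F_dn), state$f_dn, pairs_dn))
}

# central finite-difference gradient of the backend energy over kappa pairs
fd_gradient <- function(backend, state, pairs_up, pairs_dn, h = 1e-5) {
  n <- nrow(pairs_up) + nrow(pairs_dn)
  vapply(seq_len(n), function(k) {
    e <- numeric(n)
    e[k] <- h
    (energy_at_kappa(backend, state, pairs_up, pairs_dn, e) -
       energy_at_kappa(backend, state, pairs_up, pairs_dn, -e)) / (2 * h)
  }, numeric(1))
}
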