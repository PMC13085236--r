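# Orbital representation, exponential parametrization, gradients, residual.

test_that("kappa_pairs enumerates nonredundant pairs", {
  f <- c(1, 1, 0, 0)
  p <- kappa_pairs(f)
  expect_equal(nrow(p), 4)
  expect_true(all(f[p[, 1]] != f[p[, 2]]))
  expect_true(all(p[, 1] < p[, 2]))
  expect_equal(nrow(kappa_pairs(f, redundant = TRUE)), 6)
  expect_equal(nrow(kappa_pairs(f, subset = c(1, 3))), 1)
  expect_equal(nrow(kappa_pairs(c(1, 1))), 0)
  expect_equal(nrow(kappa_pairs(1)), 0)
})

test_that("expm_antihermitian: identity, closed-form 2x2, series oracle", {
  expect_equal(expm_antihermitian(matrix(0, 3, 3)), diag(3))
  th <- pi / 2
  K <- matrix(c(0, -th, th, 0), 2, 2)
  U <- expm_antihermitian(K)
  # 90-degree rotation: columns swapped up to sign
  expect_equal(abs(U), matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-12)
  # closed-form planar rotation for K[1,2] = a
  a <- 0.37
  K2 <- matrix(c(0, -a, a, 0), 2, 2)
  expect_equal(expm_antihermitian(K2),
               matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2),
               tolerance = 1e-13)
  # power-series oracle, 50 terms, random 6x6
  K6 <- random_kappa(6, seed = 42)
  S <- diag(6); term <- diag(6)
  for (n in 1:50) {
    term <- term %*% K6 / n
    S <- S + term
  }
  U6 <- expm_antihermitian(K6)
  expect_lt(max(abs(U6 - S)), 1e-12)
  expect_lt(max(abs(crossprod(U6) - diag(6))), 1e-12)
})

test_that("expm_antihermitian rejects bad input", {
  expect_error(expm_antihermitian(matrix(1, 2, 2)), "antisymmetric")
  expect_error(expm_antihermitian(matrix(c(0, NA, NA, 0), 2, 2)))
})

test_that("apply_unitary: identity, swap, composition, re-referencing", {
  b <- random_backend(7)
  st <- random_state(b, seed = 2)
  M <- st$M
  same <- apply_unitary(st, matrix(0, M, M), matrix(0, M, M))
  expect_equal(same$C_up, st$C_up)
  expect_equal(same$C_dn, st$C_dn)
  # pi/2 in pair (1,2) exchanges the orbitals up to sign
  K <- matrix(0, M, M); K[1, 2] <- pi / 2; K[2, 1] <- -pi / 2
  sw <- apply_unitary(st, K, NULL)
  expect_equal(abs(sw$C_up[, 1]), abs(st$C_up[, 2]), tolerance = 1e-12)
  expect_equal(abs(sw$C_up[, 2]), abs(st$C_up[, 1]), tolerance = 1e-12)
  # composition: two half-steps equal one full step for a single-pair kappa
  Kh <- K / 2
  two <- apply_unitary(apply_unitary(st, Kh, NULL), Kh, NULL)
  expect_equal(two$C_up, sw$C_up, tolerance = 1e-12)
  # re-referencing: the rotated orbitals become the new reference
  expect_equal(sw$C0_up, sw$C_up)
  # orthonormality preserved
  expect_lt(orthonormality_error(sw), 1e-12)
})

test_that("mo_hamiltonian: identity case, triple-loop oracle, hermiticity", {
  set.seed(5)
  M <- 5
  A <- matrix(rnorm(M * M), M, M); H_AO <- (A + t(A)) / 2
  expect_equal(mo_hamiltonian(diag(M), H_AO), H_AO)
  C <- random_orthogonal(M, seed = 6)
  H <- mo_hamiltonian(C, H_AO)
  oracle <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M) for (mu in 1:M) for (nu in 1:M)
    oracle[i, j] <- oracle[i, j] + C[mu, i] * H_AO[mu, nu] * C[nu, j]
  expect_lt(max(abs(H - oracle)), 1e-13)
  expect_equal(H, t(H))
  expect_error(mo_hamiltonian(C, matrix(0, 3, 3)), "mismatch")
})

test_that("electronic_gradient: stationary and equal-occupation cases", {
  f <- c(1, 1, 0, 0)
  pairs <- kappa_pairs(f)
  expect_equal(electronic_gradient(diag(c(1, 2, 3, 4)), f, pairs),
               rep(0, nrow(pairs)))
  # equal-occupation pairs have zero gradient by the occupation factor
  all_pairs <- kappa_pairs(f, redundant = TRUE)
  set.seed(8)
  A <- matrix(rnorm(16), 4, 4); H <- (A + t(A)) / 2
  g <- electronic_gradient(H, f, all_pairs)
  eq <- f[all_pairs[, 1]] == f[all_pairs[, 2]]
  expect_equal(g[eq], rep(0, sum(eq)))
  # formula: g_ij = 2 (f_j - f_i) H_ij
  expect_equal(g, 2 * (f[all_pairs[, 2]] - f[all_pairs[, 1]]) * H[all_pairs])
})

test_that("gradient matches dE/dtheta in a 2-orbital 1-electron model", {
  spec <- ppp_dimer_spec(n_donor = 1, n_acceptor = 1, R = 4, t_DA = 0.3,
                         U_p = 0.5, alpha_acceptor = -0.2,
                         z_p = c(1, 0), n_up = 1, n_dn = 0)
  b <- ppp_backend(spec)
  st <- orbital_state(diag(2), diag(2), c(1, 0), c(0, 0))
  pairs <- kappa_pairs(st$f_up)
  ev <- backend_evaluate(b, st)
  g <- electronic_gradient(mo_hamiltonian(st$C_up, ev$F_up), st$f_up, pairs)
  h <- 1e-5
  scan_E <- function(th) {
    K <- matrix(c(0, -th, th, 0), 2, 2)
    backend_evaluate(b, apply_unitary(st, K, NULL))$energy
  }
  expect_equal(g[1], (scan_E(h) - scan_E(-h)) / (2 * h), tolerance = 1e-8)
})

test_that("master oracle: analytic gradient vs finite differences", {
  for (seed in 1:6) {
    b <- random_backend(seed)
    st <- random_state(b, seed = seed + 100)
    pu <- kappa_pairs(st$f_up); pd <- kappa_pairs(st$f_dn)
    g <- analytic_gradient(b, st, pu, pd)
    g_fd <- fd_gradient(b, st, pu, pd)
    expect_lt(max(abs(g - g_fd)), 1e-7)
  }
})

test_that("diagonal_hessian follows the occupation-energy formula", {
  eps <- c(-1, -0.5, 0.2, 0.8)
  f <- c(1, 1, 0, 0)
  pairs <- kappa_pairs(f, redundant = TRUE)
  d <- diagonal_hessian(eps, f, pairs)
  expect_equal(d, 2 * (eps[pairs[, 1]] - eps[pairs[, 2]]) *
                 (f[pairs[, 2]] - f[pairs[, 1]]))
  eq <- f[pairs[, 1]] == f[pairs[, 2]]
  expect_equal(d[eq], rep(0, sum(eq)))
  # aufbau: all occupied below all virtual -> strictly positive
  expect_true(all(d[!eq] > 0))
})

test_that("ks_residual: zero block, single coupling, gradient identity", {
  f_occ <- c(1, 1, 0, 0)
  Hd <- diag(c(-1, -0.5, 0.3, 0.9))
  expect_equal(ks_residual(Hd, Hd, f_occ, f_occ, 4), 0)
  # one occupied-virtual coupling h with N electrons: r = h^2 ev^2 / N
  h <- 0.02
  H1 <- Hd; H1[1, 3] <- H1[3, 1] <- h
  expect_equal(ks_residual(H1, Hd, f_occ, f_occ, 4),
               h^2 * HARTREE_EV^2 / 4, tolerance = 1e-12)
  # identity: r = (ev^2 / 4N) * sum g^2 over active pairs (|f_j - f_i| = 1)
  set.seed(11)
  A <- matrix(rnorm(16), 4, 4); H <- (A + t(A)) / 2
  pairs <- kappa_pairs(f_occ)
  g <- electronic_gradient(H, f_occ, pairs)
  expect_equal(ks_residual(H, Hd, f_occ, f_occ, 4),
               (sum(g^2) / 4) * HARTREE_EV^2 / 4, tolerance = 1e-12)
  expect_error(ks_residual(H, Hd, f_occ, f_occ, 0), "positive")
})

test_that("subspace_diagonalize: invariance, oracle, sign convention", {
  b <- random_backend(13)
  st <- random_state(b, seed = 14)
  e0 <- backend_evaluate(b, st)$energy
  sd <- subspace_diagonalize(st, b)
  # energy invariant under equal-occupation rotations
  expect_equal(backend_evaluate(b, sd$state)$energy, e0, tolerance = 1e-12)
  # H diagonal within each equal-occupation block afterwards
  ev <- backend_evaluate(b, sd$state)
  H <- mo_hamiltonian(sd$state$C_up, ev$F_up)
  for (val in unique(st$f_up)) {
    blk <- which(st$f_up == val)
    sub <- H[blk, blk, drop = FALSE]
    expect_lt(max(abs(sub - diag(diag(sub), length(blk)))), 1e-10)
    # eigenvalues match the dense block oracle
    H0 <- mo_hamiltonian(st$C_up, backend_evaluate(b, st)$F_up)
    expect_equal(sort(diag(sub)),
                 sort(eigen(H0[blk, blk], symmetric = TRUE)$values),
                 tolerance = 1e-10)
  }
  # reported eps match the diagonal
  expect_equal(sd$eps_up, diag(H), tolerance = 1e-10)
  # idempotence up to sign: already block-diagonal input is unchanged
  sd2 <- subspace_diagonalize(sd$state, b)
  expect_equal(abs(sd2$state$C_up), abs(sd$state$C_up), tolerance = 1e-8)
  # sign convention: largest-magnitude component of each column positive
  for (j in seq_len(st$M)) {
    col <- sd$state$C_up[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("orbital_state validates input and orthonormality_error works", {
  expect_error(orbital_state(diag(3), diag(3), c(1, 0, 0), c(2, 0, 0)))
  st <- orbital_state(diag(3), diag(3), c(1, 0, 0), c(1, 0, 0))
  expect_equal(orthonormality_error(st), 0)
  st$C_up[1, 1] <- 1.1
  expect_gt(orthonormality_error(st), 0.1)
})
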