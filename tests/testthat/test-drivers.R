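# End-to-end drivers: ground state, freeze-and-release, MOM baseline.

test_that("run_settings validates its arguments", {
  expect_error(run_settings(tol_full = -1), "positive")
  expect_error(run_settings(tol_full = 1e-6, tol_constrained = 1e-8),
               "tighter")
  s <- run_settings()
  expect_equal(s$tol_full, 4e-8)
  expect_equal(s$tol_constrained, 4e-3)
  expect_equal(s$max_iter, 333L)
})

test_that("ground_state matches the fixed-point SCF oracle", {
  # 2-site symmetric closed-shell dimer
  spec <- ppp_dimer_spec(n_donor = 1, n_acceptor = 1, R = 3, t_DA = 0.3,
                         U_p = 0.5, alpha_acceptor = 0)
  b <- ppp_backend(spec)
  gs <- ground_state(b)
  ref <- scf_fixed_point(b)
  expect_true(gs$converged)
  expect_true(ref$converged)
  expect_equal(gs$energy, ref$energy, tolerance = 1e-9)
  # random instances: energy agreement and stationarity at exit
  # deep-convergence settings make the exit gradient norm meaningful
  deep <- run_settings(tol_full = 1e-18)
  for (seed in 1:5) {
    b <- random_backend(seed + 200)
    gs <- ground_state(b, deep)
    ref <- scf_fixed_point(b)
    expect_true(gs$converged)
    expect_lt(abs(gs$energy - ref$energy), 1e-9)
    pu <- kappa_pairs(gs$state$f_up); pd <- kappa_pairs(gs$state$f_dn)
    g <- analytic_gradient(b, gs$state, pu, pd)
    expect_lt(sqrt(sum(g^2)), 1e-8)
    expect_lte(gs$residual, deep$tol_full)
  }
})

test_that("initial_guess swaps occupations and raises the energy", {
  b <- random_backend(51)
  gs <- ground_state(b)
  exc <- homo_lumo_excitation(gs)
  guess <- initial_guess(gs, exc)
  expect_equal(sum(guess$state$f_up != gs$state$f_up), 2)
  expect_identical(guess$state$C_up, gs$state$C_up)
  e_guess <- backend_evaluate(b, guess$state)$energy
  expect_gte(e_guess, gs$energy)
  # two excitations differ in four entries
  virt <- which(gs$state$f_up < 0.5)
  occ <- which(gs$state$f_up > 0.5)
  exc2 <- data.frame(hole = occ[1:2], particle = virt[1:2],
                     spin = c("up", "up"))
  g2 <- initial_guess(gs, exc2)
  expect_equal(sum(g2$state$f_up != gs$state$f_up), 4)
  expect_error(initial_guess(gs, data.frame(hole = virt[1],
                                            particle = virt[2], spin = "up")),
               "not occupied")
  expect_error(initial_guess(gs, data.frame(hole = occ[1],
                                            particle = occ[2], spin = "up")),
               "not virtual")
})

test_that("run_constrained freezes, descends, and flips the preconditioner", {
  spec <- ppp_dimer_spec(R = 20)   # charge-transfer dimer
  b <- ppp_backend(spec)
  gs <- ground_state(b)
  exc <- homo_lumo_excitation(gs)
  guess <- initial_guess(gs, exc)
  con <- run_constrained(guess, b)
  expect_true(con$converged)
  # frozen hole/particle columns never mix with relaxed orbitals: after the
  # final equal-occupation subspace diagonalization they remain exactly in
  # the span of their occupation block
  virt <- which(con$state$f_up < 0.5)
  occ <- which(con$state$f_up > 0.5)
  ph <- crossprod(con$state$C_up[, virt], guess$state$C_up[, exc$hole])
  pp <- crossprod(con$state$C_up[, occ], guess$state$C_up[, exc$particle])
  expect_equal(sum(ph^2), 1, tolerance = 1e-12)
  expect_equal(sum(pp^2), 1, tolerance = 1e-12)
  # monotone energy descent in the constrained trace
  expect_true(all(diff(con$trace$energy) <= 1e-10))
  # refreshed diagonal model has at least one negative element on the CT
  # fixture (the mechanism that drives the released saddle search uphill)
  d <- c(diagonal_hessian(con$eps_up, con$state$f_up,
                          kappa_pairs(con$state$f_up)),
         diagonal_hessian(con$eps_dn, con$state$f_dn,
                          kappa_pairs(con$state$f_dn)))
  expect_gte(sum(make_preconditioner(d) < 0), 1)
})

test_that("constrained phase with nothing frozen equals ground minimization", {
  b <- random_backend(53)
  gs <- ground_state(b)
  # aufbau occupations, empty excitation set: plain direct minimization
  guess <- structure(list(state = gs$state,
                          excitations = data.frame(hole = integer(0),
                                                   particle = integer(0),
                                                   spin = character(0)),
                          mom_ref = mom_reference(gs$state),
                          eps_up = gs$eps_up, eps_dn = gs$eps_dn,
                          ground_energy = gs$energy, ground = gs),
                     class = "frdo_guess")
  con <- run_constrained(guess, b)
  expect_equal(con$energy, gs$energy, tolerance = 1e-7)
})

test_that("run_released converges to a verified stationary saddle", {
  spec <- ppp_dimer_spec(R = 20)
  b <- ppp_backend(spec)
  fit <- frdo(b)
  expect_true(fit$converged)
  expect_gt(fit$energy, fit$ground_energy)
  pu <- kappa_pairs(fit$state$f_up); pd <- kappa_pairs(fit$state$f_dn)
  g <- analytic_gradient(b, fit$state, pu, pd)
  expect_lt(sqrt(sum(g^2)), 1e-6)
  # dense rotation scans over 3 pairs: energy extremal at angle 0
  set.seed(55)
  for (k in sample(nrow(pu), 3)) {
    sc <- rotation_scan(fit$state, b, pu[k, ], (-10:10) * 0.01,
                        spin = "up")
    i0 <- which(sc$angle == 0)
    slope <- (sc$energy[i0 + 1] - sc$energy[i0 - 1]) / 0.02
    expect_lt(abs(slope), 1e-5)
  }
  # iteration accounting: total = constrained + released
  expect_equal(fit$iterations$total,
               fit$iterations$constrained + fit$iterations$released)
  # trace covers both phases
  expect_setequal(unique(fit$trace$phase), c("constrained", "released"))
})

test_that("FR-DO and DO-MOM agree on the decoupled fixture", {
  spec <- generate_fixture(11, "decoupled")
  b <- ppp_backend(spec)
  gs <- ground_state(b)
  fr <- frdo(b, ground = gs)
  dm <- do_mom(b, ground = gs)
  expect_true(fr$converged)
  expect_true(dm$converged)
  expect_equal(fr$energy, dm$energy, tolerance = 1e-8)
  # occupations at exit: 0/1 with conserved electron counts
  expect_true(all(dm$f_up %in% c(0, 1)))
  expect_equal(sum(dm$f_up), spec$n_up)
  expect_equal(sum(dm$f_dn), spec$n_dn)
})

test_that("FR-DO is never below DO-MOM on the collapse fixture", {
  spec <- generate_fixture(1, "collapse")
  b <- ppp_backend(spec)
  gs <- ground_state(b)
  fr <- frdo(b, ground = gs)
  dm <- do_mom(b, ground = gs)
  expect_gte(fr$energy, dm$energy - 1e-8)
})

test_that("frdo is deterministic and reports positive excitation energies", {
  spec <- ppp_dimer_spec(R = 15)
  fit1 <- frdo(spec)
  fit2 <- frdo(spec)
  expect_true(fit1$converged)
  expect_gt(fit1$excitation_eV, 0)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$energy, fit2$energy)
})

test_that("dissociation_scan shows charge-transfer physics on the tail", {
  spec <- ppp_dimer_spec(t_DA = 0)
  tab <- dissociation_scan(spec, R_grid = c(10, 20, 30))
  expect_true(all(tab$converged))
  expect_true(all(diff(tab$E_CT) > 0))        # weaker hole-electron attraction
  expect_lt(abs(tab$d_CT[tab$R == 30] - 30) / 30, 0.1)
  expect_true(all(tab$E_exc_eV > 0))
})

test_that("solution methods print, summarize, plot and expose coefficients", {
  fit <- frdo(ppp_dimer_spec(R = 15))
  expect_output(print(fit), "Freeze-and-release")
  expect_output(summary(fit), "Orbital energies")
  cf <- coef(fit)
  expect_equal(dim(cf$C_up), c(4, 4))
  r <- residuals(fit)
  expect_true(is.numeric(r) && length(r) == nrow(fit$trace))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  gs <- ground_state(ppp_backend(ppp_dimer_spec(R = 15)))
  expect_output(print(gs), "Ground-state")
})
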