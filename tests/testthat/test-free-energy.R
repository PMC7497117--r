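test_that("trapezoidal TI is exact for constant and linear integrands and validates its schedule", {
  const <- lapply(1:3, function(i) rep(5, 40))
  ti <- ti_integrate(const, c(0, 0.5, 1))
  expect_equal(ti$dg, 5)
  expect_equal(ti$dg_error, 0)

  lam <- seq(0, 1, length.out = 11)
  lin <- lapply(lam, function(l) rep(2 * l, 8))
  expect_equal(ti_integrate(lin, lam)$dg, 1.0, tolerance = 1e-12)

  expect_error(ti_integrate(const, c(0, 1, 0.5)), "increasing")
  expect_error(ti_integrate(const[1:2], c(0.1, 0.9)), "coverage")
  ok <- ti_integrate(const[1:2], c(0.1, 0.9), extrapolate = TRUE)
  expect_equal(ok$dg, 5 * 0.8)
  expect_error(ti_integrate(list(rep(1, 4)), 0.5), "at least 2")
  expect_error(ti_integrate(list(rep(1, 4), numeric(0)), c(0, 1)),
               "non-empty")
})

test_that("block-averaged errors follow the Student-t construction", {
  expect_equal(block_error(rep(3.2, 100)), 0)
  # block means 1,2,3,4: s = sqrt(5/3), half-width = t975,3 * s / 2
  series <- rep(1:4, each = 25)
  expect_equal(block_error(series), qt(0.975, 3) * sqrt(5 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(block_error(series), 2.054, tolerance = 1e-3)
  expect_error(block_error(c(1, 2, 3), n_blocks = 4), "shorter")
})

test_that("harmonic alchemy by Langevin TI reproduces the analytic free energy", {
  # transform a 1-D spring a = 100 into a = 400 (energy a x^2):
  # dG = (kT/2) ln(400/100)
  lam <- seq(0, 1, length.out = 21)
  ti <- harmonic_ti_run(100, 400, lam, n_steps = 1e5, seed = 7L)
  analytic <- kbt(298) / 2 * log(4)
  expect_equal(analytic, 1.7174, tolerance = 1e-4)
  expect_lt(abs(ti$dg - analytic), ti$dg_error)
  expect_lt(ti$dg_error, 0.5)
})

test_that("swapping the alchemical endpoints flips the sign of the estimate", {
  lam <- c(0, 0.25, 0.5, 0.75, 1)
  set.seed(2)
  series <- lapply(lam, function(l) rnorm(80, mean = 3 * l - 1))
  fwd <- ti_integrate(series, lam)
  bwd <- ti_integrate(lapply(rev(series), function(s) -s), rev(1 - lam))
  expect_equal(bwd$dg, -fwd$dg, tolerance = 1e-12)
  expect_equal(bwd$dg_error, fwd$dg_error, tolerance = 1e-12)
})

test_that("staged and direct alchemical paths agree within their combined intervals", {
  # free energy is a state function: 100 -> 400 directly vs via 200
  lam <- seq(0, 1, length.out = 11)
  direct <- harmonic_ti_run(100, 400, lam, n_steps = 2e4, seed = 11L)
  s1 <- harmonic_ti_run(100, 200, lam, n_steps = 2e4, seed = 12L)
  s2 <- harmonic_ti_run(200, 400, lam, n_steps = 2e4, seed = 13L)
  staged <- s1$dg + s2$dg
  staged_err <- s1$dg_error + s2$dg_error
  expect_lt(abs(direct$dg - staged), direct$dg_error + staged_err)
})

test_that("the analytic restraint-release term obeys its exact identities and matches quadrature", {
  br <- anchor_restraints(ks = c(8000, 800, 800, 800, 800, 800))

  # standard-volume additivity: doubling V changes dG by -kT ln 2
  d <- boresch_analytic(br, standard_volume = 2 * 1.661) -
    boresch_analytic(br)
  expect_equal(d, -kbt(298) * log(2), tolerance = 1e-8)

  # scaling all six k by 4 changes dG by -kT ln(4^3)
  br4 <- anchor_restraints(ks = 4 * c(8000, 800, 800, 800, 800, 800))
  expect_equal(boresch_analytic(br4) - boresch_analytic(br),
               -kbt(298) * log(4^3), tolerance = 1e-8)

  # stiff-spring regime: numerical configurational integral within 1%
  num <- oracle_boresch_numeric(br)
  ana <- boresch_analytic(br)
  expect_lt(abs(num - ana) / abs(ana), 0.01)

  br0 <- anchor_restraints()
  br0$k_phi_b <- 0
  expect_error(boresch_analytic(br0), "positive")
})

test_that("cycle assembly enforces leg completeness and combines uncertainties additively", {
  zero <- assemble_cycle(list(dg_compl = fe_term(0), dg_lig = fe_term(0),
                              dg_restr_off = 0))
  expect_equal(zero$dg_bind, fe_term(0, 0))

  expect_error(assemble_cycle(list(dg_coul_c = fe_term(1),
                                   dg_lj_c = fe_term(1),
                                   dg_lig = fe_term(0),
                                   dg_restr_off = 0)),
               "complex leg.*dg_restr_on_c")
  expect_error(assemble_cycle(list(dg_compl = fe_term(1),
                                   dg_coul_l = fe_term(1),
                                   dg_restr_off = 0)),
               "ligand leg.*dg_lj_l")
  expect_error(assemble_cycle(list(dg_compl = fe_term(1),
                                   dg_lig = fe_term(0))),
               "restraint leg")
  expect_error(assemble_cycle(list(dg_compl = fe_term(1),
                                   dg_lig = fe_term(0),
                                   dg_restr_off = fe_term(-31.3, 2))),
               "analytic")

  quad <- assemble_cycle(list(dg_compl = fe_term(10, 3),
                              dg_lig = fe_term(-5, 4),
                              dg_restr_off = -1),
                         error_method = "quadrature")
  expect_equal(quad$dg_bind[["error"]], 5)
  lin <- assemble_cycle(list(dg_compl = fe_term(10, 3),
                             dg_lig = fe_term(-5, 4),
                             dg_restr_off = -1))
  expect_equal(lin$dg_bind[["error"]], 7)
  expect_equal(lin$dg_bind[["value"]], 4)
})
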