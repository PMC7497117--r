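test_that("reaction-field constants and cutoff behaviour match the closed form", {
  p <- rf_params(eps_rf = 80, r_cut = 1.2)
  expect_equal(p$k_rf, 79 / (161 * 1.2^3), tolerance = 1e-12)
  expect_equal(p$k_rf, 0.28397, tolerance = 1e-4)

  # vanishes continuously at the cutoff, zero beyond
  expect_equal(coulomb_rf_energy(1.2, 1, -1, p), 0, tolerance = 1e-12)
  expect_equal(coulomb_rf_energy(1.3, 1, -1, p), 0)
  r <- 0.5
  hand <- 138.935458 * 1 * -1 * (1 / r + p$k_rf * r^2 - p$c_rf)
  expect_equal(coulomb_rf_energy(r, 1, -1, p), hand)
  expect_error(coulomb_rf_energy(0, 1, 1, p), "positive")

  expect_equal(lj_energy(0.34, 0.34, 0.5), 0)
  expect_equal(lj_energy(2, 0.34, 0.5, r_cut = 1.2), 0)
  expect_error(lj_energy(-1, 0.34, 0.5), "positive")
})

test_that("soft-core LJ hits both endpoints exactly and stays finite at r = 0", {
  sig <- 0.34; eps <- 0.5
  grid <- seq(0.25, 1.5, length.out = 200)

  sc1 <- softcore_lj(grid, sig, eps, lambda = 1)
  expect_equal(sc1$energy, lj_energy(grid, sig, eps), tolerance = 1e-12)

  sc0 <- softcore_lj(c(0, grid), sig, eps, lambda = 0)
  expect_true(all(sc0$energy == 0))

  # r = 0, alpha = 0.5, p = 1, lambda = 0.5: A = 0.25 sigma^6,
  # U = 4 eps 0.5 (16 - 4) = 24 eps
  sc <- softcore_lj(0, sig, eps, lambda = 0.5)
  expect_equal(sc$energy, 24 * eps, tolerance = 1e-12)
  expect_true(is.finite(sc$energy))
  expect_error(softcore_lj(0, sig, eps, lambda = 1), "singular")

  # uniform convergence to plain LJ as lambda -> 1
  sup <- vapply(c(0.9, 0.99, 0.999), function(l) {
    max(abs(softcore_lj(grid, sig, eps, l)$energy / l -
              lj_energy(grid, sig, eps)))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
})

test_that("the analytic soft-core lambda-derivative matches central differences", {
  sig <- 0.33; eps <- 0.4
  h <- 1e-6
  set.seed(3)
  for (lam in c(0.2, 0.5, 0.8)) {
    r <- runif(5, 0.05, 1.2)
    a <- softcore_lj(r, sig, eps, lam)
    up <- softcore_lj(r, sig, eps, lam + h)$energy
    dn <- softcore_lj(r, sig, eps, lam - h)$energy
    fd <- (up - dn) / (2 * h)
    expect_equal(a$dudl, fd, tolerance = 1e-6)
  }
})

test_that("Boresch restraint energy is the six-term harmonic sum with wrapped dihedrals", {
  xyz <- anchor_xyz()
  br <- anchor_restraints()
  expect_equal(boresch_energy(xyz, br), 0, tolerance = 1e-12)
  expect_equal(boresch_energy(xyz + 100, br, lambda = 0), 0)

  # displaced configuration vs a term-by-term hand sum
  set.seed(6)
  disp <- xyz + matrix(rnorm(18, sd = 0.05), 6, 3)
  wrap <- function(d) {
    w <- (d + pi) %% (2 * pi) - pi
    ifelse(w == -pi, pi, w)
  }
  hand <- 0.5 * br$k_r * (sqrt(sum((disp[3, ] - disp[4, ])^2)) - br$r0)^2 +
    0.5 * br$k_theta_a *
      (t_angle(disp[2, ], disp[3, ], disp[4, ]) - br$theta_a0)^2 +
    0.5 * br$k_theta_b *
      (t_angle(disp[3, ], disp[4, ], disp[5, ]) - br$theta_b0)^2 +
    0.5 * br$k_phi_a *
      wrap(t_dihedral(disp[1, ], disp[2, ], disp[3, ], disp[4, ]) -
             br$phi_a0)^2 +
    0.5 * br$k_phi_b *
      wrap(t_dihedral(disp[2, ], disp[3, ], disp[4, ], disp[5, ]) -
             br$phi_b0)^2 +
    0.5 * br$k_phi_c *
      wrap(t_dihedral(disp[3, ], disp[4, ], disp[5, ], disp[6, ]) -
             br$phi_c0)^2
  expect_equal(boresch_energy(disp, br), hand, tolerance = 1e-10)
  expect_equal(boresch_energy(disp, br, lambda = 0.3), 0.3 * hand,
               tolerance = 1e-10)

  # collinear anchors make the angle undefined
  bad <- xyz
  bad[2, ] <- c(0, 0.5, 0); bad[3, ] <- c(0, 0.25, 0); bad[4, ] <- c(0, 0, 0)
  br2 <- anchor_restraints()
  expect_error(boresch_energy(rbind(bad[1, ], c(0, 0.5, 0), c(0, 0.25, 0),
                                    c(0, 0, 0), bad[5, ], bad[6, ]), br2),
               "collinear")

  expect_error(boresch_restraints(c(1, 1, 3, 4, 5, 6), 0.5, 1.5, 1.5,
                                  0, 0, 0, 1, 1, 1, 1, 1, 1), "distinct")
})

test_that("restraint definitions round-trip through the key-value text format", {
  br <- anchor_restraints()
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# restraint block",
    paste("anchors", paste(br$anchors, collapse = " ")),
    paste("r0", br$r0),
    paste("theta_a0", br$theta_a0), paste("theta_b0", br$theta_b0),
    paste("phi_a0", br$phi_a0), paste("phi_b0", br$phi_b0),
    paste("phi_c0", br$phi_c0),
    paste("k_r", br$k_r),
    paste("k_theta_a", br$k_theta_a), paste("k_theta_b", br$k_theta_b),
    paste("k_phi_a", br$k_phi_a), paste("k_phi_b", br$k_phi_b),
    paste("k_phi_c", br$k_phi_c)), path)
  br2 <- read_boresch(path)
  expect_equal(br2, br, tolerance = 1e-12)
})

test_that("the mixed Hamiltonian's lambda-derivative is U_A - U_B for linear terms and respects flags", {
  const_term <- lambda_term_linear(function(x) 3, function(x) 1)
  for (lam in c(0, 0.3, 1)) {
    h <- lambda_hamiltonian(lam, list(const_term))
    expect_equal(du_dlambda(h, NULL), 2)
    expect_equal(hamiltonian_energy(h, NULL), lam * 3 + (1 - lam) * 1)
  }

  off <- lambda_term_linear(function(x) 3, function(x) 1, scaled = FALSE)
  h <- lambda_hamiltonian(0.5, list(off))
  expect_equal(du_dlambda(h, NULL), 0)
  expect_equal(hamiltonian_energy(h, NULL), 3)
  expect_equal(du_dlambda(lambda_hamiltonian(0.5, list()), NULL), 0)

  # custom soft-core term agrees with finite differences of its energy
  sig <- 0.3; eps <- 0.4
  sc_term <- lambda_term_custom(
    energy_fn = function(x, lam) sum(softcore_lj(x, sig, eps, lam)$energy),
    dudl_fn = function(x, lam) sum(softcore_lj(x, sig, eps, lam)$dudl),
    label = "lj")
  r <- c(0.12, 0.35, 0.6)
  lam <- 0.4; hh <- 1e-6
  hham <- lambda_hamiltonian(lam, list(sc_term))
  fd <- (hamiltonian_energy(lambda_hamiltonian(lam + hh, list(sc_term)), r) -
           hamiltonian_energy(lambda_hamiltonian(lam - hh, list(sc_term)),
                              r)) / (2 * hh)
  expect_equal(du_dlambda(hham, r), fd, tolerance = 1e-6)

  # endpoint identities of the mixing
  ua <- function(x) 7; ub <- function(x) -2
  expect_equal(hamiltonian_energy(
    lambda_hamiltonian(1, list(lambda_term_linear(ua, ub))), NULL), 7)
  expect_equal(hamiltonian_energy(
    lambda_hamiltonian(0, list(lambda_term_linear(ua, ub))), NULL), -2)
})
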