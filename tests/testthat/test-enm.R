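test_that("network construction applies backbone and cutoff rules", {
  # 3 collinear beads, spacing 0.5 nm
  s <- ca_structure(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.0, 0, 0)))
  topo <- build_enm(s, params = enm_params(r_c = 1.2))
  expect_equal(nrow(topo$bonds), 3L)
  bb <- topo$bonds[topo$bonds$backbone, ]
  expect_equal(unname(as.matrix(bb[, c("i", "j")])),
               rbind(c(1, 2), c(2, 3)))
  expect_true(all(bb$k == 5e4))
  nb <- topo$bonds[!topo$bonds$backbone, ]
  expect_equal(c(nb$i, nb$j), c(1, 3))
  expect_equal(nb$k, 160)
  expect_equal(nb$r0, 1.0)

  # tighter cutoff drops the 1-3 spring (native distance 1.0 > 0.9)
  topo2 <- build_enm(s, params = enm_params(r_c = 0.9))
  expect_equal(nrow(topo2$bonds), 2L)
  expect_true(all(topo2$bonds$backbone))

  # 30-bead fixture equals the all-pairs oracle
  s30 <- make_toy_complex(30, seed = 1)
  topo30 <- build_enm(s30)
  orc <- oracle_enm_bonds(calpha_coords(s30), seq_len(30),
                          k_b = 5e4, k_nb = 160, r_c = 1.2)
  expect_equal(topo30$bonds[, c("i", "j", "k", "r0")], orc,
               ignore_attr = TRUE)
})

test_that("network energy follows k(r - r0)^2 per unordered pair and is rigid-motion invariant", {
  # isolate one non-bonded spring: middle residue atomistic
  s <- ca_structure(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.0, 0, 0)),
                    ligand_xyz = rbind(c(0.5, 0.1, 0)))
  mp <- select_atomistic(s, 1)
  expect_equal(mp$atomistic, 2L)
  topo <- build_enm(s, mp)
  expect_equal(nrow(topo$bonds), 1L)
  expect_equal(enm_energy(topo, topo$bead_xyz), 0)
  stretched <- rbind(c(0, 0, 0), c(1.1, 0, 0))
  expect_equal(enm_energy(topo, stretched), 160 * 0.1^2, tolerance = 1e-12)

  s12 <- make_toy_complex(12, seed = 4)
  topo12 <- build_enm(s12)
  set.seed(8)
  disp <- topo12$bead_xyz + matrix(rnorm(36, sd = 0.05), 12, 3)
  expect_equal(enm_energy(topo12, disp),
               oracle_enm_energy(topo12$bonds, disp))
  expect_gte(enm_energy(topo12, disp), 0)

  R <- random_rotation()
  moved <- disp %*% t(R) + rep(c(1, -2, 0.5), each = 12)
  expect_equal(enm_energy(topo12, moved), enm_energy(topo12, disp),
               tolerance = 1e-10)
})

test_that("analytic forces agree with finite differences of the energy", {
  s <- make_toy_complex(6, seed = 5)
  topo <- build_enm(s)
  set.seed(2)
  x <- topo$bead_xyz + matrix(rnorm(18, sd = 0.04), 6, 3)
  f <- enm_forces(topo, x)
  h <- 1e-6
  for (probe in list(c(1, 1), c(3, 2), c(6, 3))) {
    xp <- x; xp[probe[1], probe[2]] <- xp[probe[1], probe[2]] + h
    xm <- x; xm[probe[1], probe[2]] <- xm[probe[1], probe[2]] - h
    fd <- -(enm_energy(topo, xp) - enm_energy(topo, xm)) / (2 * h)
    expect_equal(f[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
})

test_that("the Hessian is symmetric, matches finite differences, and carries exactly the rigid-body zero modes", {
  s <- make_toy_complex(4, seed = 3)
  topo <- build_enm(s)
  H <- enm_hessian(topo)
  expect_equal(H, t(H), tolerance = 1e-14)

  Hfd <- oracle_hessian_fd(topo)
  expect_equal(H, Hfd, tolerance = 1e-4)

  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 6L)
  expect_true(all(ev > -1e-8 * max(ev)))  # positive semidefinite
})

test_that("RMSF from the Hessian obeys equipartition and harmonic scaling", {
  # one soft dof with E = a x^2, a = 160: <x^2> = kT / (2a)
  H <- diag(c(320, 1e9, 1e9))
  r <- rmsf_from_hessian(H, temperature = 298, rigid_modes = 0L)
  expect_equal(r^2, kbt(298) / 320, tolerance = 1e-6)
  expect_equal(r^2, 7.743e-3, tolerance = 1e-3)

  s <- make_toy_complex(10, seed = 5)
  topo <- build_enm(s)
  r1 <- rmsf_from_hessian(enm_hessian(topo))
  topo4 <- topo
  topo4$bonds$k <- 4 * topo4$bonds$k
  r4 <- rmsf_from_hessian(enm_hessian(topo4))
  expect_equal(r4, r1 / 2, tolerance = 1e-10)

  # a fragmented network (extra floppy modes) is reported, not silently
  # pseudo-inverted
  far <- ca_structure(rbind(c(0, 0, 0), c(0.38, 0, 0),
                            c(5, 5, 5), c(5.38, 5, 5)))
  mp <- drs_mapping(integer(0), 1:4, rep(1, 4))
  topo_far <- build_enm(far, params = enm_params())
  # beads 2-3 are chain-consecutive so still bonded; break that manually
  topo_far$bonds <- topo_far$bonds[!(topo_far$bonds$i == 2 &
                                       topo_far$bonds$j == 3), ]
  expect_error(rmsf_from_hessian(enm_hessian(topo_far)),
               "ill-conditioned")
})

test_that("k_nb fitting recovers a planted constant and reacts correctly to rescaled references", {
  s <- make_toy_complex(12, seed = 10)
  ref <- enm_rmsf(s)$rmsf  # generated with k_nb = 160
  fit <- fit_knb(s, reference_rmsf = ref)
  expect_gte(fit$k_nb, 144)
  expect_lte(fit$k_nb, 176)
  expect_lt(fit$rmse, 1e-4)

  # doubling the reference softens the fitted spring (RMSF ~ k^-1/2)
  fit2 <- fit_knb(s, reference_rmsf = 2 * ref)
  expect_lt(fit2$k_nb, fit$k_nb)

  expect_error(fit_knb(s, reference_rmsf = rep(0, 12)), "positive")
  expect_error(fit_knb(s, reference_rmsf = ref[-1]), "length")
})
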