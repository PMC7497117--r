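# Independent oracles used by the unit and acceptance tests. These follow
# brute-force or first-principles routes (direct summation, numerical
# quadrature, Metropolis Monte Carlo) deliberately distinct from the
# package's implementation paths.

# brute-force residue/ligand minimum heavy-atom distance scan
oracle_contacts <- function(structure, cutoff) {
  lig <- structure$ligand
  lig <- lig[lig$element != "H", , drop = FALSE]
  hits <- integer()
  for (i in seq_len(n_residues(structure))) {
    ra <- residue_atoms(structure, i)
    ra <- ra[ra$element != "H", , drop = FALSE]
    dmin <- Inf
    for (a in seq_len(nrow(ra))) {
      for (b in seq_len(nrow(lig))) {
        d <- sqrt((ra$x[a] - lig$x[b])^2 + (ra$y[a] - lig$y[b])^2 +
                    (ra$z[a] - lig$z[b])^2)
        dmin <- min(dmin, d)
      }
    }
    if (dmin > 0 && dmin <= cutoff) hits <- c(hits, i)
  }
  hits
}

# exhaustive COM-to-closest-ligand-atom ranking
oracle_ranking <- function(structure) {
  n <- n_residues(structure)
  d <- numeric(n)
  for (i in seq_len(n)) {
    ra <- residue_atoms(structure, i)
    com <- c(sum(ra$mass * ra$x), sum(ra$mass * ra$y),
             sum(ra$mass * ra$z)) / sum(ra$mass)
    best <- Inf
    for (b in seq_len(nrow(structure$ligand))) {
      lb <- c(structure$ligand$x[b], structure$ligand$y[b],
              structure$ligand$z[b])
      best <- min(best, sqrt(sum((com - lb)^2)))
    }
    d[i] <- best
  }
  order(d, seq_len(n))
}

# all-pairs bond scan for the elastic network
oracle_enm_bonds <- function(xyz, residues, k_b, k_nb, r_c) {
  out <- NULL
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r0 <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (residues[j] - residues[i] == 1L) {
        out <- rbind(out, c(i, j, k_b, r0))
      } else if (r0 < r_c) {
        out <- rbind(out, c(i, j, k_nb, r0))
      }
    }
  }
  colnames(out) <- c("i", "j", "k", "r0")
  as.data.frame(out)
}

# per-bond direct summation of the network energy
oracle_enm_energy <- function(bonds, xyz) {
  e <- 0
  for (row in seq_len(nrow(bonds))) {
    r <- sqrt(sum((xyz[bonds$i[row], ] - xyz[bonds$j[row], ])^2))
    e <- e + bonds$k[row] * (r - bonds$r0[row])^2
  }
  e
}

# Hessian by central finite differences of the energy
oracle_hessian_fd <- function(topology, h = 1e-5) {
  x0 <- as.numeric(t(topology$bead_xyz))
  nd <- length(x0)
  ener <- function(v) enm_energy(topology, matrix(v, ncol = 3, byrow = TRUE))
  H <- matrix(0, nd, nd)
  for (a in seq_len(nd)) {
    for (b in a:nd) {
      xpp <- x0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm <- x0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp <- x0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm <- x0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- (ener(xpp) - ener(xpm) - ener(xmp) + ener(xmm)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# Boltzmann Monte-Carlo RMSF: Metropolis single-bead moves on the network
# energy, frames superposed onto the native structure (Kabsch via
# bio3d::fit.xyz), fluctuations measured about the aligned mean.
oracle_mc_rmsf <- function(topology, temperature = 298, n_sweeps = 40000L,
                           step = 0.035, record_every = 10L, seed = 99L,
                           burn_in = 2000L) {
  kT <- kbt(temperature)
  x <- topology$bead_xyz
  n <- nrow(x)
  b <- topology$bonds
  # bonds touching each bead
  touch <- lapply(seq_len(n), function(i) which(b$i == i | b$j == i))
  bead_energy <- function(x, i, bl) {
    dv <- x[b$i[bl], , drop = FALSE] - x[b$j[bl], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    sum(b$k[bl] * (r - b$r0[bl])^2)
  }
  set.seed(seed)
  frames <- matrix(NA_real_, (n_sweeps - burn_in) %/% record_every, 3 * n)
  k <- 0L
  for (sw in seq_len(n_sweeps)) {
    for (i in sample.int(n)) {
      bl <- touch[[i]]
      e0 <- bead_energy(x, i, bl)
      old <- x[i, ]
      x[i, ] <- old + rnorm(3, sd = step)
      e1 <- bead_energy(x, i, bl)
      if (runif(1) >= exp(-(e1 - e0) / kT)) x[i, ] <- old
    }
    if (sw > burn_in && (sw - burn_in) %% record_every == 0L) {
      k <- k + 1L
      frames[k, ] <- as.numeric(t(x))
    }
  }
  # bio3d xyz convention (x1,y1,z1,...) matches t(x) flattening
  ref <- as.numeric(t(topology$bead_xyz))
  aligned <- bio3d::fit.xyz(fixed = ref, mobile = frames,
                            fixed.inds = seq_len(3 * n),
                            mobile.inds = seq_len(3 * n))
  mu <- colMeans(aligned)
  dev2 <- sweep(aligned, 2, mu)^2
  per_dof <- colMeans(dev2)
  sqrt(colSums(matrix(per_dof, 3, n)))
}

# numerical restrained configurational integral for the Boresch term:
# the six restrained coordinates are separable, each handled by 1-D
# quadrature with its geometric measure
oracle_boresch_numeric <- function(br, temperature = 298,
                                   standard_volume = 1.661) {
  kT <- kbt(temperature)
  beta <- 1 / kT
  z_r <- stats::integrate(function(r) {
    r^2 * exp(-beta * 0.5 * br$k_r * (r - br$r0)^2)
  }, lower = 0, upper = br$r0 + 20 / sqrt(beta * br$k_r),
  rel.tol = 1e-10)$value
  z_ang <- function(k, th0) {
    stats::integrate(function(th) {
      sin(th) * exp(-beta * 0.5 * k * (th - th0)^2)
    }, lower = 0, upper = pi, rel.tol = 1e-10)$value
  }
  z_dih <- function(k) {
    stats::integrate(function(dphi) {
      exp(-beta * 0.5 * k * dphi^2)
    }, lower = -pi, upper = pi, rel.tol = 1e-10)$value
  }
  z6 <- z_r * z_ang(br$k_theta_a, br$theta_a0) *
    z_ang(br$k_theta_b, br$theta_b0) *
    z_dih(br$k_phi_a) * z_dih(br$k_phi_b) * z_dih(br$k_phi_c)
  -kT * log(8 * pi^2 * standard_volume / z6)
}

# WCA pair forces for the toy-fluid objective (helper, analytic)
wca_fluid_potential <- function(n_part, sigma, epsilon, k_conf = 50) {
  rc <- 2^(1 / 6) * sigma
  function(xflat) {
    x <- matrix(xflat, n_part, 3, byrow = TRUE)
    e <- k_conf * sum(x^2)
    f <- -2 * k_conf * x
    for (i in seq_len(n_part - 1)) {
      for (j in (i + 1):n_part) {
        dv <- x[i, ] - x[j, ]
        r <- sqrt(sum(dv^2))
        if (r < rc) {
          sr6 <- (sigma / r)^6
          e <- e + 4 * epsilon * (sr6^2 - sr6) + epsilon
          fmag <- 4 * epsilon * (12 * sr6^2 - 6 * sr6) / r
          fv <- fmag * dv / r
          f[i, ] <- f[i, ] + fv
          f[j, ] <- f[j, ] - fv
        }
      }
    }
    list(energy = e, force = as.numeric(t(f)))
  }
}

# swelling of a harmonically confined WCA droplet (mean squared distance
# of the particles from the trap center): a density-like observable that
# grows monotonically with the core scale factor c (fixed seed)
wca_fluid_objective <- function(c, rg = 0.35, epsilon = 0.34,
                                n_part = 14L, seed = 11L) {
  sigma <- rg * c
  pot <- wca_fluid_potential(n_part, sigma, epsilon)
  set.seed(seed)
  x0 <- matrix(rnorm(3 * n_part, sd = 0.35), n_part, 3)
  sys <- langevin_system(pot, masses = 18, x0 = x0)
  res <- langevin_run(sys, sim_params(n_steps = 1500L, sample_stride = 5L,
                                      seed = seed),
                      record = function(x) mean(x^2),
                      save_trajectory = FALSE)
  mean(res$observable[-(1:50)])
}

# harmonic alchemy: transform a 1-D spring a_start (lambda = 0) into
# a_end (lambda = 1) with linear mixing, sampling dU/dlambda by Langevin
# dynamics at each lambda
harmonic_ti_run <- function(a_start, a_end, lambdas, n_steps, seed,
                            temperature = 298) {
  series <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    ham <- lambda_hamiltonian(lam, list(
      lambda_term_linear(u_A = function(x) a_end * sum(x^2),
                         u_B = function(x) a_start * sum(x^2))
    ))
    a_mix <- lam * a_end + (1 - lam) * a_start
    sys <- langevin_system(
      potential = function(x) list(energy = a_mix * sum(x^2),
                                   force = -2 * a_mix * x),
      masses = 1, x0 = 0)
    out <- langevin_run(sys,
                        sim_params(temperature = temperature,
                                   n_steps = n_steps, sample_stride = 1L,
                                   seed = seed * 1000L + li),
                        record = function(x) du_dlambda(ham, x),
                        save_trajectory = FALSE)
    series[[li]] <- out$observable
  }
  ti_integrate(series, lambdas)
}
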