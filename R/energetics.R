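#' Soft-core parameters
#'
#' Beutler-style soft-core modification of the Lennard-Jones potential,
#' with radius-softening strength `alpha` and lambda power `p`.
#'
#' @param alpha dimensionless (default 0.5).
#' @param p lambda exponent (default 1.0).
#' @export
softcore_params <- function(alpha = 0.5, p = 1.0) {
  stopifnot(alpha >= 0, p > 0)
  base::structure(list(alpha = alpha, p = p), class = "drs_softcore")
}

#' Reaction-field electrostatics parameters
#'
#' @param eps_rf dielectric constant of the continuum beyond the cutoff
#'   (default 80).
#' @param r_cut cutoff, nm (default 1.2).
#' @export
rf_params <- function(eps_rf = 80, r_cut = 1.2) {
  stopifnot(eps_rf >= 1, r_cut > 0)
  k_rf <- (eps_rf - 1) / ((2 * eps_rf + 1) * r_cut^3)
  c_rf <- 1 / r_cut + k_rf * r_cut^2
  base::structure(list(eps_rf = eps_rf, r_cut = r_cut,
                       k_rf = k_rf, c_rf = c_rf),
                  class = "drs_rf")
}

#' Lennard-Jones pair energy
#'
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, truncated (zero) beyond
#' `r_cut`. Vectorized over `r`.
#'
#' @param r separation, nm (> 0).
#' @param sigma nm.
#' @param epsilon kJ/mol.
#' @param r_cut truncation radius, nm (default `Inf`).
#' @return kJ/mol.
#' @export
lj_energy <- function(r, sigma, epsilon, r_cut = Inf) {
  if (any(r <= 0)) stop("separation must be positive")
  sr6 <- (sigma / r)^6
  ifelse(r <= r_cut, 4 * epsilon * (sr6^2 - sr6), 0)
}

#' Reaction-field Coulomb pair energy
#'
#' \eqn{U(r) = f q_i q_j (1/r + k_{rf} r^2 - c_{rf})} for \eqn{r \le
#' r_{cut}} and zero beyond, with \eqn{k_{rf} = (\epsilon_{rf}-1) /
#' ((2\epsilon_{rf}+1) r_{cut}^3)} and \eqn{c_{rf} = 1/r_{cut} + k_{rf}
#' r_{cut}^2}; the shift makes the energy vanish continuously at the
#' cutoff. Vectorized over `r`.
#'
#' @inheritParams lj_energy
#' @param q_i,q_j charges, e.
#' @param params an [rf_params()].
#' @return kJ/mol.
#' @export
coulomb_rf_energy <- function(r, q_i, q_j, params = rf_params()) {
  if (any(r <= 0)) stop("separation must be positive")
  u <- COULOMB_F * q_i * q_j * (1 / r + params$k_rf * r^2 - params$c_rf)
  ifelse(r <= params$r_cut, u, 0)
}

#' Soft-core Lennard-Jones energy and its lambda-derivative
#'
#' Beutler form: with \eqn{A = \alpha\sigma^6(1-\lambda)^p + r^6},
#' \eqn{U = 4\epsilon\lambda[(\sigma^6/A)^2 - \sigma^6/A]}. The potential
#' is finite at r = 0 for lambda < 1 and reduces exactly to plain
#' Lennard-Jones at lambda = 1. The analytic \eqn{\partial U/\partial
#' \lambda} is returned alongside the energy. Vectorized over `r`.
#'
#' @param r separation, nm (>= 0; r = 0 allowed when `lambda < 1`).
#' @param sigma nm.
#' @param epsilon kJ/mol.
#' @param lambda coupling parameter in [0, 1].
#' @param sc a [softcore_params()].
#' @return list with `energy` and `dudl`, both kJ/mol.
#' @export
softcore_lj <- function(r, sigma, epsilon, lambda, sc = softcore_params()) {
  stopifnot(lambda >= 0, lambda <= 1, all(r >= 0))
  if (lambda == 1 && any(r == 0)) {
    stop("r = 0 is singular at lambda = 1 (plain Lennard-Jones limit)")
  }
  s6 <- sigma^6
  A <- sc$alpha * s6 * (1 - lambda)^sc$p + r^6
  term <- s6^2 / A^2 - s6 / A
  energy <- 4 * epsilon * lambda * term
  # dA/dlambda = -alpha s6 p (1-lambda)^(p-1)
  dA <- -sc$alpha * s6 * sc$p * (1 - lambda)^(sc$p - 1)
  dterm <- (-2 * s6^2 / A^3 + s6 / A^2) * dA
  dudl <- 4 * epsilon * (term + lambda * dterm)
  list(energy = energy, dudl = dudl)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# angle at p2 between vectors (p1-p2) and (p3-p2), radians
.angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (sqrt(sum(.cross3(u, v)^2)) < 1e-10 * nu * nv) {
    stop("geometry error: collinear anchor triple, angle undefined")
  }
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv))))
}

# dihedral p1-p2-p3-p4, radians in (-pi, pi]
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# smallest signed difference x - x0 wrapped to (-pi, pi]
.wrap_angle <- function(dx) {
  w <- (dx + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Boresch-style orientational restraints
#'
#' One distance, two angles and three dihedrals defined on three protein
#' anchor atoms (a, b, c) and three ligand anchor atoms (A, B, C):
#' r = |a-A|, thetaA = angle(b, a, A), thetaB = angle(a, A, B),
#' phiA = dihedral(c, b, a, A), phiB = dihedral(b, a, A, B),
#' phiC = dihedral(a, A, B, C). Each term is harmonic with the 1/2 k
#' convention.
#'
#' @param anchors integer length-6: rows into the configuration matrix for
#'   (c, b, a, A, B, C) ordered protein-to-ligand along the anchor chain;
#'   names `p3, p2, p1, l1, l2, l3` are used in this package, with `p1-l1`
#'   the restrained distance.
#' @param r0 reference distance, nm.
#' @param theta_a0,theta_b0 reference angles, rad (strictly inside
#'   (0, pi)).
#' @param phi_a0,phi_b0,phi_c0 reference dihedrals, rad.
#' @param k_r distance force constant, kJ mol^-1 nm^-2.
#' @param k_theta_a,k_theta_b angle force constants, kJ mol^-1 rad^-2.
#' @param k_phi_a,k_phi_b,k_phi_c dihedral force constants,
#'   kJ mol^-1 rad^-2.
#' @export
boresch_restraints <- function(anchors, r0, theta_a0, theta_b0,
                               phi_a0, phi_b0, phi_c0,
                               k_r, k_theta_a, k_theta_b,
                               k_phi_a, k_phi_b, k_phi_c) {
  anchors <- as.integer(anchors)
  if (length(anchors) != 6L || anyDuplicated(anchors)) {
    stop("anchors must be 6 distinct atom indices")
  }
  ks <- c(k_r, k_theta_a, k_theta_b, k_phi_a, k_phi_b, k_phi_c)
  if (any(ks < 0)) stop("force constants must be non-negative")
  if (theta_a0 <= 0 || theta_a0 >= pi || theta_b0 <= 0 || theta_b0 >= pi) {
    stop("reference angles must lie strictly inside (0, pi)")
  }
  base::structure(
    list(anchors = anchors, r0 = r0,
         theta_a0 = theta_a0, theta_b0 = theta_b0,
         phi_a0 = phi_a0, phi_b0 = phi_b0, phi_c0 = phi_c0,
         k_r = k_r, k_theta_a = k_theta_a, k_theta_b = k_theta_b,
         k_phi_a = k_phi_a, k_phi_b = k_phi_b, k_phi_c = k_phi_c),
    class = "drs_boresch")
}

#' Boresch restraint energy
#'
#' \eqn{\lambda \sum \frac{1}{2} k (x - x_0)^2} over the restrained
#' distance, two angles and three dihedrals; dihedral deviations are
#' wrapped to the smallest signed difference in (-pi, pi].
#'
#' @param xyz configuration matrix (n x 3, nm) containing at least the
#'   anchor atoms.
#' @param restraints a [boresch_restraints()].
#' @param lambda restraint coupling in [0, 1] (default 1).
#' @return kJ/mol.
#' @export
boresch_energy <- function(xyz, restraints, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda == 0) return(0)
  an <- restraints$anchors
  p3 <- xyz[an[1], ]; p2 <- xyz[an[2], ]; p1 <- xyz[an[3], ]
  l1 <- xyz[an[4], ]; l2 <- xyz[an[5], ]; l3 <- xyz[an[6], ]
  r <- sqrt(sum((p1 - l1)^2))
  th_a <- .angle(p2, p1, l1)
  th_b <- .angle(p1, l1, l2)
  ph_a <- .dihedral(p3, p2, p1, l1)
  ph_b <- .dihedral(p2, p1, l1, l2)
  ph_c <- .dihedral(p1, l1, l2, l3)
  e <- 0.5 * restraints$k_r * (r - restraints$r0)^2 +
    0.5 * restraints$k_theta_a * (th_a - restraints$theta_a0)^2 +
    0.5 * restraints$k_theta_b * (th_b - restraints$theta_b0)^2 +
    0.5 * restraints$k_phi_a * .wrap_angle(ph_a - restraints$phi_a0)^2 +
    0.5 * restraints$k_phi_b * .wrap_angle(ph_b - restraints$phi_b0)^2 +
    0.5 * restraints$k_phi_c * .wrap_angle(ph_c - restraints$phi_c0)^2
  lambda * e
}

#' Read Boresch restraints from a key-value text block
#'
#' Plain-text format, one `key value` pair per line; keys: `anchors`
#' (six indices), `r0`, `theta_a0`, `theta_b0`, `phi_a0`, `phi_b0`,
#' `phi_c0`, `k_r`, `k_theta_a`, `k_theta_b`, `k_phi_a`, `k_phi_b`,
#' `k_phi_c`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [boresch_restraints()].
#' @export
read_boresch <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) as.numeric(x[-1]))
  names(vals) <- keys
  boresch_restraints(
    anchors = vals$anchors, r0 = vals$r0,
    theta_a0 = vals$theta_a0, theta_b0 = vals$theta_b0,
    phi_a0 = vals$phi_a0, phi_b0 = vals$phi_b0, phi_c0 = vals$phi_c0,
    k_r = vals$k_r, k_theta_a = vals$k_theta_a,
    k_theta_b = vals$k_theta_b, k_phi_a = vals$k_phi_a,
    k_phi_b = vals$k_phi_b, k_phi_c = vals$k_phi_c)
}

#' Mixed alchemical Hamiltonian
#'
#' \eqn{U_\lambda = \lambda U_A + (1-\lambda) U_B} over a list of terms.
#' Two kinds of term are supported: linearly mixed terms (an A-side and a
#' B-side energy function of the configuration; their lambda-derivative is
#' \eqn{U_A - U_B}) and custom terms (e.g. pairwise soft-core sums) that
#' supply their own energy and analytic derivative as functions of
#' (configuration, lambda). A term whose `scaled` flag is off contributes
#' its A-side energy at full strength and zero to the derivative.
#'
#' @param lambda value in [0, 1]; lambda = 1 is the A endpoint and
#'   lambda = 0 the B endpoint.
#' @param terms list of terms from [lambda_term_linear()] or
#'   [lambda_term_custom()].
#' @export
lambda_hamiltonian <- function(lambda, terms) {
  stopifnot(lambda >= 0, lambda <= 1, is.list(terms))
  ok <- vapply(terms, inherits, TRUE, what = "drs_lambda_term")
  if (length(terms) && !all(ok)) stop("terms must be lambda terms")
  base::structure(list(lambda = lambda, terms = terms),
                  class = "drs_hamiltonian")
}

#' @rdname lambda_hamiltonian
#' @param u_A,u_B energy functions of the configuration, kJ/mol.
#' @param scaled logical; if `FALSE` the term is held at its A-side value
#'   and excluded from the lambda-derivative.
#' @param label optional term label (e.g. `"coulomb"`, `"lj"`,
#'   `"restraints"`).
#' @export
lambda_term_linear <- function(u_A, u_B, scaled = TRUE, label = NULL) {
  stopifnot(is.function(u_A), is.function(u_B))
  base::structure(list(kind = "linear", u_A = u_A, u_B = u_B,
                       scaled = scaled, label = label),
                  class = "drs_lambda_term")
}

#' @rdname lambda_hamiltonian
#' @param energy_fn function(x, lambda) -> kJ/mol.
#' @param dudl_fn function(x, lambda) -> kJ/mol, the analytic
#'   lambda-derivative of `energy_fn`.
#' @export
lambda_term_custom <- function(energy_fn, dudl_fn, scaled = TRUE,
                               label = NULL) {
  stopifnot(is.function(energy_fn), is.function(dudl_fn))
  base::structure(list(kind = "custom", energy_fn = energy_fn,
                       dudl_fn = dudl_fn, scaled = scaled, label = label),
                  class = "drs_lambda_term")
}

#' Total energy of a mixed Hamiltonian at its current lambda
#'
#' @param hamiltonian a [lambda_hamiltonian()].
#' @param x configuration (whatever the term energy functions accept).
#' @return kJ/mol.
#' @export
hamiltonian_energy <- function(hamiltonian, x) {
  lam <- hamiltonian$lambda
  e <- 0
  for (t in hamiltonian$terms) {
    e <- e + if (t$kind == "linear") {
      if (t$scaled) lam * t$u_A(x) + (1 - lam) * t$u_B(x) else t$u_A(x)
    } else {
      if (t$scaled) t$energy_fn(x, lam) else t$energy_fn(x, 1)
    }
  }
  e
}

#' Analytic lambda-derivative of a mixed Hamiltonian
#'
#' For linearly mixed terms this is \eqn{U_A(x) - U_B(x)}; custom terms
#' supply their own analytic derivative. Unscaled terms contribute zero.
#'
#' @inheritParams hamiltonian_energy
#' @return kJ/mol.
#' @export
du_dlambda <- function(hamiltonian, x) {
  lam <- hamiltonian$lambda
  d <- 0
  for (t in hamiltonian$terms) {
    if (!t$scaled) next
    d <- d + if (t$kind == "linear") t$u_A(x) - t$u_B(x)
             else t$dudl_fn(x, lam)
  }
  d
}
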