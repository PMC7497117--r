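#' Elastic-network parameters
#'
#' Two spring species act between C-alpha beads: a stiff backbone constant
#' `k_b` between chain-consecutive beads (applied regardless of distance),
#' and a weaker constant `k_nb` between all other bead pairs whose native
#' separation lies below the cutoff `r_c`. The bond energy convention is
#' \eqn{k (r - r_0)^2} (no 1/2 factor), i.e. each constant is twice the
#' conventional 1/2-k spring constant.
#'
#' @param k_b backbone spring constant, kJ mol^-1 nm^-2 (default 5e4).
#' @param k_nb non-bonded spring constant, kJ mol^-1 nm^-2 (default 160).
#' @param r_c native-distance cutoff, nm (default 1.2).
#' @return object of class `drs_enm_params`.
#' @export
enm_params <- function(k_b = 5e4, k_nb = 160, r_c = 1.2) {
  stopifnot(k_b > 0, k_nb >= 0, r_c > 0)
  structure(list(k_b = k_b, k_nb = k_nb, r_c = r_c),
            class = "drs_enm_params")
}

#' Build the C-alpha elastic network for the coarse-grained region
#'
#' Beads sit at the native C-alpha positions of the coarse-grained
#' residues. Chain-consecutive beads (residue indices differing by 1) are
#' connected with `k_b`; every other pair is connected with `k_nb` if and
#' only if its native distance is below `r_c` (Heaviside on the native
#' distance). Native bond lengths are taken from the reference
#' conformation.
#'
#' @param structure a [drs_structure()]; every CG residue must have a CA.
#' @param mapping a [drs_mapping()], or `NULL` to treat every residue as
#'   coarse-grained (used when parameterizing the network on the whole
#'   protein).
#' @param params an [enm_params()].
#' @return object of class `drs_enm`: `bead_xyz` (N x 3 native positions,
#'   nm), `bonds` (data.frame `i`, `j`, `k`, `r0`), `residue` (bead to
#'   residue index).
#' @export
build_enm <- function(structure, mapping = NULL, params = enm_params()) {
  n <- n_residues(structure)
  cg_res <- if (is.null(mapping)) seq_len(n) else sort(mapping$cg)
  ca_flag <- tapply(structure$atoms$is_calpha, structure$atoms$residue, any)
  if (!all(ca_flag[cg_res])) {
    stop("structural error: CG residue(s) without a CA atom: ",
         paste(cg_res[!ca_flag[cg_res]], collapse = ", "))
  }
  xyz <- calpha_coords(structure)[cg_res, , drop = FALSE]
  nb <- length(cg_res)
  if (nb < 2L) stop("elastic network needs at least 2 beads")

  d <- .cross_dist(xyz, xyz)
  ii <- jj <- integer(); kk <- r0 <- numeric(); bb <- logical()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      consecutive <- (cg_res[j] - cg_res[i]) == 1L
      if (consecutive) {
        ii <- c(ii, i); jj <- c(jj, j)
        kk <- c(kk, params$k_b); r0 <- c(r0, d[i, j]); bb <- c(bb, TRUE)
      } else if (d[i, j] < params$r_c) {
        ii <- c(ii, i); jj <- c(jj, j)
        kk <- c(kk, params$k_nb); r0 <- c(r0, d[i, j]); bb <- c(bb, FALSE)
      }
    }
  }
  base::structure(list(bead_xyz = unname(xyz),
                       bonds = data.frame(i = ii, j = jj, k = kk, r0 = r0,
                                          backbone = bb),
                       residue = cg_res, params = params),
                  class = "drs_enm")
}

#' @export
print.drs_enm <- function(x, ...) {
  nb <- nrow(x$bead_xyz)
  back <- sum(x$bonds$backbone)
  cat(sprintf("elastic network: %d beads, %d bonds (%d backbone, %d other)\n",
              nb, nrow(x$bonds), back, nrow(x$bonds) - back))
  invisible(x)
}

# coerce positions argument to an N x 3 matrix matching the topology
.enm_positions <- function(topology, positions) {
  n <- nrow(topology$bead_xyz)
  if (is.null(dim(positions))) {
    if (length(positions) != 3L * n) stop("positions length must be 3N")
    positions <- matrix(positions, n, 3, byrow = TRUE)
  }
  if (!all(dim(positions) == c(n, 3L))) {
    stop("positions must be an N x 3 matrix matching the topology")
  }
  positions
}

#' Elastic-network potential energy
#'
#' \eqn{E = \sum_{i<j} k_{ij} (r_{ij} - r^0_{ij})^2} over the bond list
#' (each unordered pair counted once, no 1/2 factor).
#'
#' @param topology a `drs_enm` from [build_enm()].
#' @param positions N x 3 matrix of bead positions, nm (or length-3N
#'   vector in bead-major order).
#' @return energy in kJ/mol.
#' @export
enm_energy <- function(topology, positions) {
  x <- .enm_positions(topology, positions)
  b <- topology$bonds
  dv <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  sum(b$k * (r - b$r0)^2)
}

#' Elastic-network forces
#'
#' Analytic negative gradient of [enm_energy()].
#'
#' @inheritParams enm_energy
#' @return N x 3 matrix of forces, kJ mol^-1 nm^-1.
#' @export
enm_forces <- function(topology, positions) {
  x <- .enm_positions(topology, positions)
  b <- topology$bonds
  dv <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  # dE/dr = 2 k (r - r0); force on i points along -dv when stretched
  fx <- dv * (-2 * b$k * (r - b$r0) / r)
  f <- matrix(0, nrow(x), 3)
  for (row in seq_len(nrow(b))) {
    f[b$i[row], ] <- f[b$i[row], ] + fx[row, ]
    f[b$j[row], ] <- f[b$j[row], ] - fx[row, ]
  }
  f
}

#' Hessian of the elastic network at the native state
#'
#' Second-derivative matrix of [enm_energy()] evaluated at the reference
#' (native) bead positions, where each bond contributes
#' \eqn{2 k \, \hat u \hat u^T} on its 3x3 blocks. The result is symmetric
#' and positive semidefinite with the rigid-body modes at zero.
#'
#' @param topology a `drs_enm`.
#' @return 3N x 3N matrix, kJ mol^-1 nm^-2 (dof order: bead 1 x,y,z,
#'   bead 2 x,y,z, ...).
#' @export
enm_hessian <- function(topology) {
  x <- topology$bead_xyz
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 beads")
  H <- matrix(0, 3 * n, 3 * n)
  b <- topology$bonds
  for (row in seq_len(nrow(b))) {
    i <- b$i[row]; j <- b$j[row]
    dv <- x[i, ] - x[j, ]
    r <- sqrt(sum(dv^2))
    u <- dv / r
    blk <- 2 * b$k[row] * (tcrossprod(u) +
      (1 - b$r0[row] / r) * (diag(3) - tcrossprod(u)))
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, ri] <- H[ri, ri] + blk
    H[rj, rj] <- H[rj, rj] + blk
    H[ri, rj] <- H[ri, rj] - blk
    H[rj, ri] <- H[rj, ri] - blk
  }
  (H + t(H)) / 2
}

#' Thermal C-alpha fluctuations from the network Hessian
#'
#' The equilibrium covariance of a harmonic network is
#' \eqn{C = k_B T \, H^+} with \eqn{H^+} the pseudo-inverse over the
#' non-rigid modes; the per-bead RMSF is the square root of the trace of
#' the bead's 3x3 diagonal block of C. Modes with eigenvalue below
#' `1e-8 * max(eigenvalue)` are treated as rigid-body modes and excluded;
#' more such modes than `rigid_modes` signals an ill-conditioned network.
#'
#' @param hessian 3N x 3N matrix from [enm_hessian()].
#' @param temperature K (default 298).
#' @param rigid_modes expected number of zero modes (6 for a non-collinear
#'   3-D network).
#' @return numeric vector of per-bead RMSF values, nm.
#' @export
rmsf_from_hessian <- function(hessian, temperature = 298, rigid_modes = 6L) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian),
            nrow(hessian) %% 3 == 0)
  eig <- eigen(hessian, symmetric = TRUE)
  thr <- 1e-8 * max(eig$values)
  keep <- eig$values > thr
  n_zero <- sum(!keep)
  if (n_zero > rigid_modes) {
    stop("ill-conditioned network: ", n_zero,
         " near-zero modes (expected at most ", rigid_modes, ")")
  }
  V <- eig$vectors[, keep, drop = FALSE]
  w <- kbt(temperature) / eig$values[keep]
  # diagonal of C = V diag(w) V^T without forming C
  diagC <- rowSums(sweep(V^2, 2, w, "*"))
  n <- nrow(hessian) / 3
  sqrt(colSums(matrix(diagC, 3, n)))
}

#' Predicted C-alpha RMSF of a structure's elastic network
#'
#' Convenience wrapper: build the network, form its Hessian and return the
#' per-bead RMSF.
#'
#' @inheritParams build_enm
#' @param temperature K.
#' @return data.frame with columns `residue` and `rmsf` (nm).
#' @export
enm_rmsf <- function(structure, mapping = NULL, params = enm_params(),
                     temperature = 298) {
  topo <- build_enm(structure, mapping, params)
  data.frame(residue = topo$residue,
             rmsf = rmsf_from_hessian(enm_hessian(topo), temperature))
}

# golden-section minimization of f on [lo, hi] to relative tolerance rtol
.golden_min <- function(f, lo, hi, rtol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while ((b - a) > rtol * (abs(a) + abs(b)) / 2 && (b - a) > 1e-12) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Fit the non-bonded spring constant to a reference RMSF profile
#'
#' Minimizes the root-mean-square error between the network-predicted
#' C-alpha RMSF and a reference per-residue profile, over `k_nb` only
#' (`k_b` and `r_c` held fixed). The search is golden-section on
#' log10(k_nb) over [1e-1, 1e6] kJ mol^-1 nm^-2 to a relative tolerance of
#' 1e-3.
#'
#' @inheritParams build_enm
#' @param reference_rmsf numeric vector of reference per-bead RMSF values
#'   (nm), one per CG bead, all positive.
#' @param temperature K.
#' @return list with `k_nb` (fitted value), `rmse` (at the optimum) and
#'   `params` (an [enm_params()] carrying the fitted constant).
#' @export
fit_knb <- function(structure, mapping = NULL, reference_rmsf,
                    params = enm_params(), temperature = 298) {
  topo0 <- build_enm(structure, mapping, params)
  nb <- nrow(topo0$bead_xyz)
  if (length(reference_rmsf) != nb) {
    stop("reference_rmsf length (", length(reference_rmsf),
         ") must equal the number of beads (", nb, ")")
  }
  if (any(!is.finite(reference_rmsf)) || any(reference_rmsf <= 0)) {
    stop("reference RMSF values must be positive and finite")
  }
  is_nb <- !topo0$bonds$backbone
  objective <- function(log10k) {
    topo <- topo0
    topo$bonds$k[is_nb] <- 10^log10k
    pred <- rmsf_from_hessian(enm_hessian(topo), temperature)
    sqrt(mean((pred - reference_rmsf)^2))
  }
  best <- .golden_min(objective, -1, 6, rtol = 1e-3)
  k_nb <- 10^best
  list(k_nb = k_nb, rmse = objective(best),
       params = enm_params(k_b = params$k_b, k_nb = k_nb, r_c = params$r_c))
}

#' Write / read an RMSF profile as a two-column table
#'
#' @param rmsf data.frame with columns `residue` and `rmsf` (nm).
#' @param path file path.
#' @export
write_rmsf <- function(rmsf, path) {
  write.table(rmsf[, c("residue", "rmsf")], path, row.names = FALSE,
              quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_rmsf
#' @export
read_rmsf <- function(path) {
  read.table(path, header = TRUE, col.names = c("residue", "rmsf"))
}

#' Dump an elastic-network topology as CSV
#'
#' Columns `i`, `j`, `k` (kJ mol^-1 nm^-2) and `r0` (nm).
#'
#' @param topology a `drs_enm`.
#' @param path file path.
#' @export
write_enm <- function(topology, path) {
  write.csv(topology$bonds[, c("i", "j", "k", "r0")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
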