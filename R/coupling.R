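#' Weeks-Chandler-Andersen excluded-volume energy
#'
#' The purely repulsive WCA potential: the Lennard-Jones potential cut at
#' its minimum \eqn{2^{1/6}\sigma} and shifted up by \eqn{\epsilon}, so
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma} and zero beyond. Vectorized over `r`.
#'
#' @param r separation, nm (> 0).
#' @param sigma WCA diameter, nm.
#' @param epsilon well depth of the underlying LJ, kJ/mol (default 0.34,
#'   the carbon value of common all-atom force fields).
#' @return energy, kJ/mol (non-negative).
#' @export
wca_energy <- function(r, sigma, epsilon = 0.34) {
  if (any(r <= 0)) stop("separation must be positive")
  stopifnot(sigma > 0, epsilon > 0)
  sr6 <- (sigma / r)^6
  u <- 4 * epsilon * (sr6^2 - sr6) + epsilon
  ifelse(r < 2^(1 / 6) * sigma, u, 0)
}

#' CG-bead coupling parameters
#'
#' Each coarse-grained bead repels the solvent (and the atomistic region)
#' through a WCA term whose diameter scales with the residue's radius of
#' gyration: \eqn{\sigma_i = R_{g,i} \cdot c}.
#'
#' @param structure a [drs_structure()].
#' @param mapping a [drs_mapping()], or `NULL` for an all-CG protein.
#' @param c dimensionless scale factor (default 0.658, calibrated against
#'   bulk solvent density).
#' @param epsilon WCA epsilon, kJ/mol (default 0.34).
#' @param sigma_floor minimum sigma, nm; single-atom residues with zero
#'   radius of gyration are floored here with a warning.
#' @return object of class `drs_coupling`: data.frame `table` with columns
#'   `residue`, `rg`, `sigma`, plus `epsilon` and `c`.
#' @export
assign_sigmas <- function(structure, mapping = NULL, c = 0.658,
                          epsilon = 0.34, sigma_floor = 0.05) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) {
    stop("scale factor c must be positive")
  }
  stopifnot(epsilon > 0)
  cg_res <- if (is.null(mapping)) seq_len(n_residues(structure))
            else sort(mapping$cg)
  geom <- residue_geometry_table(structure)
  rg <- geom$rg[match(cg_res, geom$residue)]
  sigma <- rg * c
  low <- sigma < sigma_floor
  if (any(low)) {
    warning(sum(low), " bead(s) with sigma below ", sigma_floor,
            " nm floored (zero/near-zero radius of gyration)")
    sigma[low] <- sigma_floor
  }
  base::structure(list(table = data.frame(residue = cg_res, rg = rg,
                                          sigma = sigma),
                       epsilon = epsilon, c = c),
                  class = "drs_coupling")
}

#' @export
print.drs_coupling <- function(x, ...) {
  cat(sprintf(
    "WCA coupling: %d beads, epsilon = %.3g kJ/mol, c = %.3f, sigma in [%.3f, %.3f] nm\n",
    nrow(x$table), x$epsilon, x$c, min(x$table$sigma), max(x$table$sigma)))
  invisible(x)
}

#' Write a coupling table as CSV
#' @param coupling a `drs_coupling`.
#' @param path file path.
#' @export
write_coupling <- function(coupling, path) {
  df <- coupling$table
  df$epsilon <- coupling$epsilon
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibrate the WCA scale factor against a target observable
#'
#' Bisection on a monotone scalar objective (for example the bulk solvent
#' density of a reference simulation as a function of `c`) until the
#' objective matches the target to a relative tolerance. Deterministic for
#' a deterministic objective.
#'
#' @param objective function of a single scalar `c`, monotone on the
#'   bracket.
#' @param target desired objective value.
#' @param bracket length-2 numeric interval; `objective(bracket) - target`
#'   must change sign across it.
#' @param tol relative tolerance on `|objective(c) - target|`
#'   (default 1e-4).
#' @param max_iter bisection iteration cap.
#' @return the calibrated scalar `c`.
#' @export
calibrate_c <- function(objective, target, bracket, tol = 1e-4,
                        max_iter = 200L) {
  stopifnot(is.function(objective), length(bracket) == 2L)
  lo <- min(bracket); hi <- max(bracket)
  flo <- objective(lo) - target
  fhi <- objective(hi) - target
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) * sign(fhi) > 0) {
    stop("calibration error: objective does not straddle the target on [",
         lo, ", ", hi, "]")
  }
  scale <- max(abs(target), 1e-12)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- objective(mid) - target
    if (abs(fm) <= tol * scale || (hi - lo) < 1e-14) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
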