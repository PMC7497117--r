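#' A free-energy term with uncertainty
#'
#' @param value kJ/mol.
#' @param error CI half-width, kJ/mol (default 0; analytic terms carry no
#'   statistical uncertainty).
#' @return named numeric `c(value, error)`.
#' @export
fe_term <- function(value, error = 0) {
  stopifnot(is.numeric(value), length(value) == 1L, error >= 0)
  c(value = value, error = error)
}

.as_fe_term <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 1L) x <- c(x, 0)
  if (length(x) != 2L || !is.numeric(x)) {
    stop("term '", what, "' must be a value or c(value, error)")
  }
  fe_term(x[[1]], x[[2]])
}

#' Block-averaged confidence-interval half-width
#'
#' The series is split into `n_blocks` contiguous blocks of equal length
#' (trailing remainder dropped); the half-width is
#' \eqn{t_{(1+conf)/2,\,n-1} \cdot s / \sqrt{n}} with `s` the standard
#' deviation of the block means.
#'
#' @param series numeric vector of correlated samples.
#' @param n_blocks number of blocks (default 4).
#' @param confidence confidence level (default 0.95, Student t).
#' @return CI half-width in the series' units.
#' @export
block_error <- function(series, n_blocks = 4L, confidence = 0.95) {
  n <- length(series)
  if (n < n_blocks) {
    stop("series length (", n, ") shorter than n_blocks (", n_blocks, ")")
  }
  bl <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(series[((b - 1) * bl + 1):(b * bl)])
  }, numeric(1))
  s <- sd(means)
  qt((1 + confidence) / 2, df = n_blocks - 1L) * s / sqrt(n_blocks)
}

#' Thermodynamic integration over a lambda schedule
#'
#' \eqn{\Delta G = \int_0^1 \langle \partial U_\lambda / \partial \lambda
#' \rangle_\lambda \, d\lambda} by the trapezoidal rule over the per-lambda
#' mean derivatives. Per-lambda uncertainties are block-averaged CI
#' half-widths and propagate linearly through the quadrature weights.
#'
#' @param series list of numeric vectors, one dU/dlambda sample series per
#'   lambda value.
#' @param lambdas strictly increasing values in [0, 1]; the endpoints 0
#'   and 1 must be present unless `extrapolate = TRUE`.
#' @param extrapolate allow a schedule without the 0/1 endpoints (the
#'   trapezoid then only covers the sampled range).
#' @param n_blocks,confidence passed to [block_error()].
#' @return object of class `drs_ti` with `lambdas`, `means`, `errors`,
#'   `dg`, `dg_error`.
#' @export
ti_integrate <- function(series, lambdas, extrapolate = FALSE,
                         n_blocks = 4L, confidence = 0.95) {
  stopifnot(is.list(series), length(series) == length(lambdas))
  if (length(lambdas) < 2L) stop("need at least 2 lambda points")
  if (any(lambdas < 0) || any(lambdas > 1)) {
    stop("lambda values must lie in [0, 1]")
  }
  if (any(diff(lambdas) <= 0)) {
    stop("lambda values must be strictly increasing")
  }
  if (any(vapply(series, length, 0L) == 0L)) {
    stop("every lambda needs a non-empty sample series")
  }
  if (!extrapolate &&
      (abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)) {
    stop("coverage error: schedule must include lambda = 0 and 1 ",
         "(set extrapolate = TRUE to integrate the sampled range only)")
  }
  means <- vapply(series, mean, numeric(1))
  errors <- vapply(series, block_error, numeric(1),
                   n_blocks = n_blocks, confidence = confidence)
  nl <- length(lambdas)
  w <- numeric(nl)
  dl <- diff(lambdas)
  w[1] <- dl[1] / 2
  w[nl] <- dl[nl - 1] / 2
  if (nl > 2L) w[2:(nl - 1)] <- (dl[-(nl - 1)] + dl[-1]) / 2
  base::structure(list(lambdas = lambdas, means = means, errors = errors,
                       weights = w,
                       dg = sum(w * means),
                       dg_error = sum(abs(w) * errors)),
                  class = "drs_ti")
}

#' @export
print.drs_ti <- function(x, ...) {
  cat(sprintf("TI over %d lambda points: dG = %.4f +/- %.4f kJ/mol\n",
              length(x$lambdas), x$dg, x$dg_error))
  invisible(x)
}

#' Default lambda schedules for the alchemical legs
#'
#' Point counts per leg: 11 (restraints on, complex), 15 (Coulomb off,
#' complex), 5 (Lennard-Jones off, complex), 5 (Coulomb on, ligand), 16
#' (Lennard-Jones on, ligand). Schedules are evenly spaced including both
#' endpoints; `interior = TRUE` selects the endpoint-free 5-point grid
#' {0.1, 0.3, 0.5, 0.7, 0.9} for the 5-point legs instead.
#'
#' @param leg one of `"restr_c"`, `"coul_c"`, `"lj_c"`, `"coul_l"`,
#'   `"lj_l"`.
#' @param interior use the literal interior grid for the 5-point legs.
#' @return numeric vector of lambda values.
#' @export
lambda_schedule <- function(leg = c("restr_c", "coul_c", "lj_c",
                                    "coul_l", "lj_l"),
                            interior = FALSE) {
  leg <- match.arg(leg)
  n <- switch(leg, restr_c = 11L, coul_c = 15L, lj_c = 5L,
              coul_l = 5L, lj_l = 16L)
  if (interior && n == 5L) return(c(0.1, 0.3, 0.5, 0.7, 0.9))
  seq(0, 1, length.out = n)
}

#' Analytic free energy of removing Boresch restraints to standard state
#'
#' The stiff-spring closed form:
#' \deqn{\Delta G_{r\_off} = -k_B T \ln\!\left[
#'   \frac{8\pi^2 V^\circ}{r_0^2 \sin\theta_{A0} \sin\theta_{B0}}
#'   \frac{\sqrt{k_r k_{\theta A} k_{\theta B} k_{\phi A} k_{\phi B}
#'   k_{\phi C}}}{(2\pi k_B T)^3} \right]}
#' i.e. the free energy of releasing a restrained ligand to the standard
#' volume. All six force constants must be strictly positive (the formula
#' diverges otherwise).
#'
#' @param restraints a [boresch_restraints()].
#' @param temperature K.
#' @param standard_volume standard-state volume, nm^3 (default 1.661,
#'   i.e. 1/(0.6022 nm^-3) for a 1 M standard state).
#' @return kJ/mol.
#' @export
boresch_analytic <- function(restraints, temperature = 298,
                             standard_volume = 1.661) {
  ks <- c(restraints$k_r, restraints$k_theta_a, restraints$k_theta_b,
          restraints$k_phi_a, restraints$k_phi_b, restraints$k_phi_c)
  if (any(ks <= 0)) {
    stop("all six force constants must be positive (formula diverges)")
  }
  sa <- sin(restraints$theta_a0); sb <- sin(restraints$theta_b0)
  if (sa <= 0 || sb <= 0) stop("reference angles must have positive sine")
  kT <- kbt(temperature)
  logarg <- log(8 * pi^2 * standard_volume) -
    log(restraints$r0^2 * sa * sb) +
    0.5 * sum(log(ks)) - 3 * log(2 * pi * kT)
  -kT * logarg
}

#' Assemble the binding thermodynamic cycle
#'
#' \eqn{\Delta G_{bind} = \Delta G_{compl} + \Delta G_{lig} +
#' \Delta G_{r\_off}}: the complex leg (restraints on, Coulomb off,
#' Lennard-Jones off), the ligand solvation leg (Coulomb on, Lennard-Jones
#' on), and the analytic restraint-removal term. Legs can be given by
#' their components or as pre-summed totals (`dg_compl`, `dg_lig`).
#' Uncertainties combine by linear addition by default; the analytic term
#' carries zero uncertainty.
#'
#' @param terms named list of terms, each a value or `c(value, error)`:
#'   either `dg_restr_on_c`, `dg_coul_c`, `dg_lj_c` or `dg_compl`; either
#'   `dg_coul_l`, `dg_lj_l` or `dg_lig`; and `dg_restr_off`.
#' @param mode `"decoupling"` (molecule-environment interactions off) or
#'   `"annihilation"` (intramolecular terms off as well). Bookkeeping is
#'   identical; the mode labels what the leg free energies mean.
#' @param error_method `"linear"` (default) or `"quadrature"` combination
#'   of component uncertainties.
#' @return object of class `drs_cycle`.
#' @export
assemble_cycle <- function(terms, mode = c("decoupling", "annihilation"),
                           error_method = c("linear", "quadrature")) {
  mode <- match.arg(mode)
  error_method <- match.arg(error_method)
  comb <- function(...) {
    ts <- list(...)
    v <- sum(vapply(ts, `[[`, 0, 1))
    e <- vapply(ts, `[[`, 0, 2)
    fe_term(v, if (error_method == "linear") sum(e) else sqrt(sum(e^2)))
  }
  g <- function(nm) .as_fe_term(terms[[nm]], nm)

  components <- list()
  if (!is.null(terms$dg_compl)) {
    compl <- g("dg_compl")
  } else {
    parts <- c("dg_restr_on_c", "dg_coul_c", "dg_lj_c")
    miss <- parts[!parts %in% names(terms)]
    if (length(miss)) {
      stop("complex leg incomplete: missing ", paste(miss, collapse = ", "))
    }
    components[parts] <- lapply(parts, g)
    compl <- do.call(comb, components[parts])
  }
  if (!is.null(terms$dg_lig)) {
    lig <- g("dg_lig")
  } else {
    parts <- c("dg_coul_l", "dg_lj_l")
    miss <- parts[!parts %in% names(terms)]
    if (length(miss)) {
      stop("ligand leg incomplete: missing ", paste(miss, collapse = ", "))
    }
    components[parts] <- lapply(parts, g)
    lig <- do.call(comb, components[parts])
  }
  if (is.null(terms$dg_restr_off)) {
    stop("restraint leg incomplete: missing dg_restr_off")
  }
  roff <- .as_fe_term(terms$dg_restr_off, "dg_restr_off")
  if (roff[["error"]] != 0) {
    stop("dg_restr_off is analytic and must carry zero uncertainty")
  }
  bind <- comb(compl, lig, roff)
  base::structure(list(mode = mode, components = components,
                       dg_compl = compl, dg_lig = lig,
                       dg_restr_off = roff, dg_bind = bind,
                       error_method = error_method),
                  class = "drs_cycle")
}

#' @export
print.drs_cycle <- function(x, ...) {
  fmt <- function(t) sprintf("%8.1f +/- %.1f", t[["value"]], t[["error"]])
  cat("binding cycle (", x$mode, "), kJ/mol\n", sep = "")
  if (length(x$components)) {
    for (nm in names(x$components)) {
      cat(sprintf("  %-14s %s\n", nm, fmt(x$components[[nm]])))
    }
  }
  cat(sprintf("  %-14s %s\n", "dG_compl", fmt(x$dg_compl)))
  cat(sprintf("  %-14s %s\n", "dG_lig", fmt(x$dg_lig)))
  cat(sprintf("  %-14s %8.1f (analytic)\n", "dG_r_off",
              x$dg_restr_off[["value"]]))
  cat(sprintf("  %-14s %s\n", "dG_bind", fmt(x$dg_bind)))
  invisible(x)
}

#' Export a cycle ledger as CSV
#'
#' One row per term: term, value, error.
#'
#' @param cycle a `drs_cycle`.
#' @param path file path.
#' @export
write_cycle <- function(cycle, path) {
  rows <- c(cycle$components,
            list(dg_compl = cycle$dg_compl, dg_lig = cycle$dg_lig,
                 dg_restr_off = cycle$dg_restr_off,
                 dg_bind = cycle$dg_bind))
  df <- data.frame(term = names(rows),
                   value = vapply(rows, `[[`, 0, 1),
                   error = vapply(rows, `[[`, 0, 2))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
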