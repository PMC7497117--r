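#' Physical constants and internal units
#'
#' All quantities in the package use molecular-simulation units:
#' lengths in nm, times in ps, energies in kJ/mol, temperatures in K,
#' charges in units of the elementary charge, masses in amu.
#'
#' @format `KB` is the Boltzmann constant in kJ/(mol K); `COULOMB_F` is the
#'   electric conversion factor \eqn{1/(4\pi\epsilon_0)} in
#'   kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.
#' @name constants
NULL

#' @rdname constants
#' @export
KB <- 0.0083144621

#' @rdname constants
#' @export
COULOMB_F <- 138.935458

#' Thermal energy
#'
#' @param temperature temperature in K.
#' @return \eqn{k_B T} in kJ/mol.
#' @export
kbt <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB * temperature
}

# standard atomic masses (amu) for elements seen in protein/ligand PDBs
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, SE = 78.971
)

#' Standard atomic mass for an element symbol
#'
#' Unknown symbols fall back to the first character of the atom name when
#' that resolves, otherwise an error is raised.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param atom_name optional character vector of atom names used as a
#'   fallback when the element column is blank or unknown.
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element, atom_name = NULL) {
  key <- toupper(trimws(as.character(element)))
  m <- .element_masses[key]
  if (!is.null(atom_name)) {
    bad <- is.na(m)
    if (any(bad)) {
      fallback <- toupper(substr(trimws(atom_name[bad]), 1L, 1L))
      m[bad] <- .element_masses[fallback]
    }
  }
  if (any(is.na(m))) {
    stop("unknown element symbol(s): ",
         paste(unique(key[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
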