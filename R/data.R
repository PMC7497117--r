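#' Published TI components for the lysozyme-chitotriose benchmark
#'
#' Component free energies of the alchemical binding cycle of hen egg-white
#' lysozyme bound to di-N-acetylchitotriose, as reported for the
#' dual-resolution model this package implements: the complex-leg Coulomb,
#' Lennard-Jones and restraint components for the fully atomistic reference
#' and for 3-10 atomistic active-site residues, the ligand solvation leg,
#' the analytic restraint-removal term, and the annihilation-route leg
#' totals. These tables serve as inputs for the worked examples: cycle
#' assembly and the mapping-quality scan recompute every derived number
#' (leg totals, binding free energies, deviations) from them.
#'
#' @return list with
#'   \describe{
#'     \item{complex}{data.frame of complex-leg components per resolution
#'       (kJ/mol; `n_at = NA` marks the fully atomistic reference).}
#'     \item{ligand}{named list of `fe_term`s `dg_coul_l`, `dg_lj_l`.}
#'     \item{dg_restr_off}{analytic restraint-removal term, kJ/mol.}
#'     \item{annihilation}{named list of `fe_term`s: ligand and complex
#'       leg totals for the two simulation engines.}
#'   }
#' @export
hewl_reference_data <- function() {
  comp <- read.csv(system.file("extdata", "hewl_complex_components.csv",
                               package = "dualres"))
  const <- read.csv(system.file("extdata", "hewl_cycle_constants.csv",
                                package = "dualres"))
  pick <- function(q) {
    r <- const[const$quantity == q, ]
    fe_term(r$value, r$error)
  }
  list(
    complex = comp,
    ligand = list(dg_coul_l = pick("dg_coul_l"),
                  dg_lj_l = pick("dg_lj_l")),
    dg_restr_off = pick("dg_restr_off")[["value"]],
    annihilation = list(
      lig_espp = pick("annihilation_lig_espp"),
      compl_espp = pick("annihilation_compl_espp"),
      lig_grom = pick("annihilation_lig_grom"),
      compl_grom = pick("annihilation_compl_grom"))
  )
}

#' Assemble the benchmark binding cycles from the shipped components
#'
#' Builds the decoupling cycle ledger for one resolution of the
#' lysozyme-chitotriose benchmark (or the fully atomistic reference) from
#' the published component free energies.
#'
#' @param n_at atomistic residue count 3-10, or `NA` for the fully
#'   atomistic reference.
#' @return a [assemble_cycle()] ledger.
#' @export
hewl_cycle <- function(n_at = NA) {
  d <- hewl_reference_data()
  row <- if (is.na(n_at)) d$complex[is.na(d$complex$n_at), ]
         else d$complex[!is.na(d$complex$n_at) & d$complex$n_at == n_at, ]
  if (nrow(row) != 1L) stop("no benchmark row for n_at = ", n_at)
  assemble_cycle(list(
    dg_coul_c = fe_term(row$dg_coul_c, row$err_coul_c),
    dg_lj_c = fe_term(row$dg_lj_c, row$err_lj_c),
    dg_restr_on_c = fe_term(row$dg_restr_on_c, row$err_restr_on_c),
    dg_coul_l = d$ligand$dg_coul_l,
    dg_lj_l = d$ligand$dg_lj_l,
    dg_restr_off = d$dg_restr_off
  ), mode = "decoupling")
}
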