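#' @importFrom graphics plot points
NULL

#' Quadratic deviation of complex-leg components from a reference
#'
#' \eqn{\delta^2 = (\Delta G_{Coul} - \Delta G_{Coul}^{ref})^2 +
#' (\Delta G_{LJ} - \Delta G_{LJ}^{ref})^2 + (\Delta G_{Restr} -
#' \Delta G_{Restr}^{ref})^2}: the unweighted sum of squared differences of
#' the complex leg's Coulomb, Lennard-Jones and restraint free-energy
#' components from the fully atomistic reference. Uncertainties do not
#' enter.
#'
#' @param row numeric length-3 `(coul, lj, restr)` components, kJ/mol.
#' @param reference numeric length-3 reference components, kJ/mol.
#' @return list with `delta_sq` ((kJ/mol)^2), `delta` (kJ/mol) and the
#'   per-term squared `components`.
#' @export
quadratic_deviation <- function(row, reference) {
  row <- as.numeric(row); reference <- as.numeric(reference)
  stopifnot(length(row) == 3L, length(reference) == 3L,
            all(is.finite(row)), all(is.finite(reference)))
  comp <- (row - reference)^2
  names(comp) <- c("coul", "lj", "restr")
  list(delta_sq = sum(comp), delta = sqrt(sum(comp)), components = comp)
}

# pull the (coul, lj, restr) complex-leg components out of a cycle
.cycle_components <- function(cycle, what) {
  need <- c("dg_coul_c", "dg_lj_c", "dg_restr_on_c")
  have <- need %in% names(cycle$components)
  if (!all(have)) {
    stop("report error: ledger '", what, "' lacks complex-leg component(s): ",
         paste(need[!have], collapse = ", "))
  }
  vapply(cycle$components[need], `[[`, 0, 1)
}

#' Scan mapping quality across resolutions
#'
#' Computes the quadratic deviation of every resolution's complex-leg
#' components from the fully atomistic reference and locates the optimal
#' atomistic residue count (smallest delta; ties go to the smaller count).
#'
#' @param ledgers named list mapping the atomistic residue count `n_at` to
#'   a [assemble_cycle()] ledger built from complex-leg components (names
#'   coercible to integer).
#' @param reference the fully atomistic reference ledger, also built from
#'   components.
#' @return object of class `drs_devreport`: data.frame `table` (columns
#'   `n_at`, `dg_coul_c`, `dg_lj_c`, `dg_restr_on_c`, `delta_sq_coul`,
#'   `delta_sq_lj`, `delta_sq_restr`, `delta_sq`, `delta`, sorted by
#'   `n_at`), `reference` components, and `optimal_n_at`.
#' @export
resolution_scan <- function(ledgers, reference) {
  if (length(ledgers) < 2L) {
    stop("need at least 2 resolutions to scan")
  }
  n_at <- as.integer(names(ledgers))
  if (any(is.na(n_at))) stop("ledger names must be atomistic counts")
  ref <- .cycle_components(reference, "reference")
  rows <- lapply(seq_along(ledgers), function(i) {
    comp <- .cycle_components(ledgers[[i]], names(ledgers)[i])
    qd <- quadratic_deviation(comp, ref)
    data.frame(n_at = n_at[i],
               dg_coul_c = comp[1], dg_lj_c = comp[2],
               dg_restr_on_c = comp[3],
               delta_sq_coul = qd$components[["coul"]],
               delta_sq_lj = qd$components[["lj"]],
               delta_sq_restr = qd$components[["restr"]],
               delta_sq = qd$delta_sq, delta = qd$delta)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$n_at), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$n_at[order(tab$delta, tab$n_at)][1]
  base::structure(list(table = tab, reference = ref,
                       optimal_n_at = best),
                  class = "drs_devreport")
}

#' @export
print.drs_devreport <- function(x, ...) {
  cat("mapping-quality scan (complex-leg deviation from fully atomistic)\n")
  print(x$table[, c("n_at", "delta_sq", "delta")], row.names = FALSE)
  cat("optimal atomistic residue count:", x$optimal_n_at, "\n")
  invisible(x)
}

#' Plot the deviation profile
#'
#' delta (kJ/mol) against the number of atomistic residues, with the
#' optimum marked.
#'
#' @param x a `drs_devreport`.
#' @param ... passed to [plot()].
#' @export
plot.drs_devreport <- function(x, ...) {
  tab <- x$table
  plot(tab$n_at, tab$delta, type = "b", pch = 19,
       xlab = "atomistic residues",
       ylab = expression(sqrt(delta^2) ~ "(kJ/mol)"), ...)
  points(tab$n_at[tab$n_at == x$optimal_n_at],
         tab$delta[tab$n_at == x$optimal_n_at], col = 2, pch = 19, cex = 1.5)
  invisible(x)
}

#' Export a deviation report as CSV
#'
#' @param report a `drs_devreport`.
#' @param path file path.
#' @export
write_devreport <- function(report, path) {
  tab <- report$table
  tab$optimal <- tab$n_at == report$optimal_n_at
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
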