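#' Resolution mapping of a dual-resolution protein
#'
#' A `drs_mapping` partitions the protein residues into an atomistic set
#' (the active-site region, ordered by increasing center-of-mass distance
#' to the closest ligand atom) and a coarse-grained remainder that becomes
#' C-alpha elastic-network beads.
#'
#' @param atomistic integer vector of atomistic residue indices, ordered by
#'   increasing ligand distance.
#' @param cg integer vector of coarse-grained residue indices.
#' @param rank_distance numeric vector, per-residue distance (nm) of the
#'   residue center of mass to the closest ligand atom, indexed by residue.
#' @return object of class `drs_mapping`.
#' @export
drs_mapping <- function(atomistic, cg, rank_distance) {
  atomistic <- as.integer(atomistic)
  cg <- as.integer(cg)
  if (length(intersect(atomistic, cg))) {
    stop("atomistic and cg sets overlap")
  }
  all_idx <- sort(c(atomistic, cg))
  if (!identical(all_idx, seq_along(rank_distance))) {
    stop("atomistic + cg must cover residues 1..N exactly")
  }
  if (is.unsorted(rank_distance[atomistic])) {
    stop("atomistic set must be ordered by increasing ligand distance")
  }
  structure(list(atomistic = atomistic, cg = sort(cg),
                 rank_distance = as.numeric(rank_distance),
                 n_at = length(atomistic)),
            class = "drs_mapping")
}

#' @export
print.drs_mapping <- function(x, ...) {
  cat(sprintf("resolution mapping: %d atomistic / %d coarse-grained\n",
              x$n_at, length(x$cg)))
  if (x$n_at) {
    cat("atomistic residues (by ligand distance): ",
        paste(x$atomistic, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Residues in direct contact with the ligand
#'
#' A residue is in contact when its minimum heavy-atom (non-hydrogen)
#' distance to any ligand atom is at or below `cutoff`.
#'
#' @param structure a [drs_structure()] with a non-empty ligand.
#' @param cutoff contact cutoff in nm (default 0.45).
#' @return sorted integer vector of contact residue indices.
#' @export
contact_residues <- function(structure, cutoff = 0.45) {
  if (nrow(structure$ligand) == 0L) {
    stop("structure has no ligand; contact detection needs one")
  }
  lig <- structure$ligand
  lig <- lig[lig$element != "H", , drop = FALSE]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  at <- structure$atoms[structure$atoms$element != "H", , drop = FALSE]
  hits <- integer()
  for (i in seq_len(n_residues(structure))) {
    ra <- at[at$residue == i, c("x", "y", "z"), drop = FALSE]
    if (!nrow(ra)) next
    dmin <- min(.cross_dist(as.matrix(ra), lxyz))
    if (dmin <= cutoff && dmin > 0) hits <- c(hits, i)
    else if (dmin == 0 && cutoff > 0) hits <- c(hits, i)
  }
  hits
}

# all pairwise distances between rows of two n x 3 matrices
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Rank residues by center-of-mass distance to the ligand
#'
#' Each residue's distance is the minimum over ligand atoms of the distance
#' between the residue center of mass and that atom. Ties are broken by
#' residue index (ascending).
#'
#' @param structure a [drs_structure()] with a non-empty ligand.
#' @return data.frame with columns `residue` and `distance` (nm), sorted by
#'   increasing distance.
#' @export
rank_by_ligand_distance <- function(structure) {
  if (nrow(structure$ligand) == 0L) {
    stop("structure has no ligand; ranking needs one")
  }
  geom <- residue_geometry_table(structure)
  lxyz <- as.matrix(structure$ligand[, c("x", "y", "z")])
  com <- as.matrix(geom[, c("x", "y", "z")])
  d <- apply(.cross_dist(com, lxyz), 1, min)
  ord <- order(d, geom$residue)
  data.frame(residue = geom$residue[ord], distance = d[ord])
}

#' Select the atomistic region by distance-ranked residue count
#'
#' The `n_at` residues closest to the ligand (center-of-mass distance to
#' the nearest ligand atom) become the atomistic region; the remainder is
#' coarse-grained. When `n_at` is at least the number of direct-contact
#' residues, the atomistic set must contain all of them; the function fails
#' if the distance ranking ever violates this.
#'
#' @param structure a [drs_structure()] with a non-empty ligand.
#' @param n_at number of atomistic residues, between 0 and N.
#' @param contact_cutoff heavy-atom contact cutoff (nm) used for the
#'   contact-coverage check.
#' @return a [drs_mapping()].
#' @export
select_atomistic <- function(structure, n_at, contact_cutoff = 0.45) {
  n <- n_residues(structure)
  if (!is.numeric(n_at) || length(n_at) != 1L || n_at < 0 || n_at > n) {
    stop("n_at must lie in [0, ", n, "]")
  }
  n_at <- as.integer(n_at)
  rk <- rank_by_ligand_distance(structure)
  atomistic <- rk$residue[seq_len(n_at)]
  cg <- setdiff(seq_len(n), atomistic)
  rank_distance <- rk$distance[order(rk$residue)]

  contacts <- contact_residues(structure, cutoff = contact_cutoff)
  if (n_at >= length(contacts) && !all(contacts %in% atomistic)) {
    stop("distance ranking does not cover all contact residues at n_at = ",
         n_at, "; missing: ",
         paste(setdiff(contacts, atomistic), collapse = ", "))
  }
  drs_mapping(atomistic, cg, rank_distance)
}

#' Write / read a mapping as a two-column table
#'
#' Plain-text serialization: one row per residue, columns `residue` and
#' `resolution` (`AT` or `CG`), plus the ranking distance.
#'
#' @param mapping a [drs_mapping()].
#' @param path file path.
#' @return `path` (write) or a `drs_mapping` (read).
#' @export
write_mapping <- function(mapping, path) {
  n <- length(mapping$rank_distance)
  df <- data.frame(
    residue = seq_len(n),
    resolution = ifelse(seq_len(n) %in% mapping$atomistic, "AT", "CG"),
    distance = mapping$rank_distance
  )
  write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  at <- df$residue[df$resolution == "AT"]
  at <- at[order(df$distance[match(at, df$residue)], at)]
  drs_mapping(at, df$residue[df$resolution == "CG"], df$distance)
}
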