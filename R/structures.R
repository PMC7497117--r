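#' @importFrom stats runif rnorm sd setNames qt var
#' @importFrom utils read.csv write.csv read.table write.table packageVersion
NULL

# three-letter codes treated as amino acids (CA atom required)
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Protein-ligand structure container
#'
#' A `drs_structure` holds the protein as a table of atoms grouped into
#' 1-based, contiguous residues, the ligand as a separate atom table, and a
#' rectangular box. Coordinates are in nm, masses in amu, charges in e.
#'
#' @param atoms data.frame with columns `residue`, `resname`, `name`,
#'   `element`, `mass`, `charge`, `x`, `y`, `z`, `is_calpha`.
#' @param ligand data.frame with columns `name`, `element`, `mass`,
#'   `charge`, `x`, `y`, `z` (zero rows allowed for apo structures).
#' @param box numeric length-3 box edge lengths in nm.
#' @return an object of class `drs_structure`.
#' @export
drs_structure <- function(atoms, ligand, box) {
  stopifnot(is.data.frame(atoms), is.data.frame(ligand),
            is.numeric(box), length(box) == 3L)
  need <- c("residue", "resname", "name", "element", "mass", "charge",
            "x", "y", "z", "is_calpha")
  if (!all(need %in% names(atoms))) {
    stop("atoms table missing columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  }
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  idx <- sort(unique(atoms$residue))
  if (!identical(idx, seq_along(idx))) {
    stop("residue indices must be 1-based and contiguous")
  }
  ca_per_res <- tapply(atoms$is_calpha, atoms$residue, sum)
  amino <- tapply(atoms$resname, atoms$residue, function(r) r[1] %in% .aa3)
  if (any(amino & ca_per_res != 1L)) {
    bad <- idx[amino & ca_per_res != 1L]
    stop("structural error: amino-acid residue(s) without exactly one CA: ",
         paste(bad, collapse = ", "))
  }
  structure(list(atoms = atoms, ligand = ligand, box = as.numeric(box)),
            class = "drs_structure")
}

#' @export
print.drs_structure <- function(x, ...) {
  cat(sprintf(
    "dual-resolution structure: %d residues (%d atoms), ligand of %d atoms\n",
    n_residues(x), nrow(x$atoms), nrow(x$ligand)))
  cat(sprintf("box: %.3f x %.3f x %.3f nm\n",
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of protein residues in a structure
#' @param structure a `drs_structure`.
#' @export
n_residues <- function(structure) {
  if (nrow(structure$atoms) == 0L) return(0L)
  max(structure$atoms$residue)
}

#' Atoms belonging to one residue
#' @param structure a `drs_structure`.
#' @param i residue index (1-based).
#' @return data.frame of the residue's atoms.
#' @export
residue_atoms <- function(structure, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n_residues(structure))
  structure$atoms[structure$atoms$residue == i, , drop = FALSE]
}

#' Center of mass and radius of gyration of a residue
#'
#' The center of mass is the mass-weighted mean position; the radius of
#' gyration is \eqn{R_g = \sqrt{\sum_i m_i |r_i - com|^2 / \sum_i m_i}}.
#' All atoms of the residue (hydrogens included) contribute.
#'
#' @param residue data.frame of atoms with columns `mass`, `x`, `y`, `z`
#'   (as returned by [residue_atoms()]).
#' @return list with `com` (length-3, nm) and `rg` (nm).
#' @export
residue_geometry <- function(residue) {
  stopifnot(is.data.frame(residue), nrow(residue) >= 1L)
  m <- residue$mass
  if (any(m <= 0) || sum(m) <= 0) stop("residue has non-positive mass")
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  list(com = unname(com), rg = sqrt(sum(m * d2) / sum(m)))
}

# COM and Rg for every residue; returns data.frame(residue, x, y, z, rg)
residue_geometry_table <- function(structure) {
  n <- n_residues(structure)
  out <- data.frame(residue = seq_len(n), x = NA_real_, y = NA_real_,
                    z = NA_real_, rg = NA_real_)
  for (i in seq_len(n)) {
    g <- residue_geometry(residue_atoms(structure, i))
    out[i, c("x", "y", "z")] <- g$com
    out$rg[i] <- g$rg
  }
  out
}

#' Cartesian coordinates of all C-alpha atoms
#' @param structure a `drs_structure`.
#' @return N x 3 matrix, nm.
#' @export
calpha_coords <- function(structure) {
  ca <- structure$atoms[structure$atoms$is_calpha, , drop = FALSE]
  ca <- ca[order(ca$residue), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$residue
  m
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses a single-model, single-chain PDB file (the first MODEL and chain
#' are taken when several are present), separates ligand atoms selected by
#' residue name, and converts coordinates from Angstrom to nm. Atom masses
#' are inferred from the element column, falling back to the first character
#' of the atom name. PDB files carry no partial charges, so charges are
#' initialized to zero.
#'
#' @param path PDB file path.
#' @param ligand_selector character vector of residue names (e.g. `"LIG"`,
#'   `"NAG"`) marking the ligand among HETATM records.
#' @return a [drs_structure()].
#' @export
read_pdb <- function(path, ligand_selector = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  short <- which(is_atom & nchar(lines) < 54L)
  if (length(short)) {
    stop("parse error: truncated ATOM/HETATM record at line ", short[1])
  }
  coords_txt <- cbind(substr(lines[is_atom], 31, 38),
                      substr(lines[is_atom], 39, 46),
                      substr(lines[is_atom], 47, 54))
  bad <- which(is.na(suppressWarnings(as.numeric(coords_txt))) |
                 coords_txt == "")
  if (length(bad)) {
    ln <- which(is_atom)[(bad[1] - 1L) %% sum(is_atom) + 1L]
    stop("parse error: malformed coordinate field at line ", ln)
  }

  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  # first chain only (single-chain support)
  chains <- unique(at$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L) {
    warning("multiple chains found; keeping chain ", chains[1])
    at <- at[is.na(at$chain) | at$chain == chains[1], , drop = FALSE]
  }

  is_lig <- at$resid %in% ligand_selector
  prot <- at[!is_lig & at$type == "ATOM", , drop = FALSE]
  lig <- at[is_lig, , drop = FALSE]

  elem <- function(df) {
    e <- if ("elesy" %in% names(df)) trimws(df$elesy) else rep("", nrow(df))
    blank <- is.na(e) | e == ""
    e[blank] <- substr(trimws(df$elety[blank]), 1L, 1L)
    e
  }

  if (nrow(prot)) {
    key <- paste(prot$resno, prot$insert)
    ridx <- match(key, unique(key))
    pe <- elem(prot)
    atoms <- data.frame(
      residue = ridx,
      resname = trimws(prot$resid),
      name = trimws(prot$elety),
      element = pe,
      mass = element_mass(pe, prot$elety),
      charge = 0,
      x = prot$x / 10, y = prot$y / 10, z = prot$z / 10,
      is_calpha = trimws(prot$elety) == "CA",
      stringsAsFactors = FALSE
    )
  } else {
    atoms <- data.frame(residue = integer(), resname = character(),
                        name = character(), element = character(),
                        mass = numeric(), charge = numeric(),
                        x = numeric(), y = numeric(), z = numeric(),
                        is_calpha = logical())
  }

  if (nrow(lig)) {
    le <- elem(lig)
    ligand <- data.frame(
      name = trimws(lig$elety), element = le,
      mass = element_mass(le, lig$elety), charge = 0,
      x = lig$x / 10, y = lig$y / 10, z = lig$z / 10,
      resname = trimws(lig$resid), stringsAsFactors = FALSE
    )
  } else {
    ligand <- data.frame(name = character(), element = character(),
                         mass = numeric(), charge = numeric(),
                         x = numeric(), y = numeric(), z = numeric(),
                         resname = character())
  }

  xyz <- rbind(as.matrix(atoms[, c("x", "y", "z")]),
               as.matrix(ligand[, c("x", "y", "z")]))
  box <- if (nrow(xyz)) apply(xyz, 2, max) - pmin(apply(xyz, 2, min), 0) + 1
         else c(1, 1, 1)
  drs_structure(atoms, ligand, box)
}

#' Write a structure to a PDB file
#'
#' Protein atoms are written as ATOM records and ligand atoms as HETATM
#' records (residue name `LIG` unless the ligand table carries its own);
#' coordinates are converted nm to Angstrom.
#'
#' @param structure a `drs_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  l <- structure$ligand
  n_a <- nrow(a); n_l <- nrow(l)
  lig_res <- if (n_l && "resname" %in% names(l)) l$resname else
    rep("LIG", n_l)
  lig_resno <- rep(n_residues(structure) + 1L, n_l)
  xyz <- c(t(rbind(as.matrix(a[, c("x", "y", "z")]),
                   as.matrix(l[, c("x", "y", "z")])))) * 10
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = c(rep("ATOM", n_a), rep("HETATM", n_l)),
    resno = c(a$residue, lig_resno),
    resid = c(a$resname, lig_res),
    eleno = seq_len(n_a + n_l),
    elety = c(a$name, l$name),
    elesy = c(a$element, l$element),
    chain = rep("A", n_a + n_l)
  )
  invisible(path)
}

# uniformly random unit 3-vector
.rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic toy protein-ligand complex
#'
#' Builds a deterministic (per seed) synthetic complex for testing and
#' demonstrations: a self-avoiding C-alpha random walk with consecutive
#' spacing 0.38 nm +/- 10%, 3-8 satellite atoms per residue around each
#' C-alpha, and a 5-20 atom ligand cluster placed within 0.5 nm of a
#' designated pocket residue. Ligand atoms carry small partial charges that
#' sum to zero; protein atoms are neutral.
#'
#' @param n_residues number of residues (>= 3).
#' @param seed RNG seed; the same seed reproduces the same structure.
#' @param pocket index of the pocket residue the ligand is attached to
#'   (default: middle of the chain).
#' @return a [drs_structure()].
#' @export
make_toy_complex <- function(n_residues, seed = 1L, pocket = NULL) {
  if (!is.numeric(n_residues) || n_residues < 3L) {
    stop("n_residues must be >= 3")
  }
  n_residues <- as.integer(n_residues)
  if (is.null(pocket)) pocket <- ceiling(n_residues / 2)
  stopifnot(pocket >= 1L, pocket <= n_residues)

  with_seed(seed, {
    # C-alpha trace: a collapsed random walk (each step biased toward the
    # centroid of the chain so far, giving a compact, globular fold),
    # rejecting steps that collide with previously placed beads (< 0.3 nm)
    ca <- matrix(0, n_residues, 3)
    for (i in 2:n_residues) {
      prev <- ca[seq_len(i - 1), , drop = FALSE]
      centroid <- colMeans(prev)
      for (try in 1:200) {
        step <- 0.38 * runif(1, 0.91, 1.09)
        pull <- centroid - ca[i - 1, ]
        np <- sqrt(sum(pull^2))
        dir <- .rand_unit() + if (np > 1e-9) 0.8 * pull / max(np, 0.5)
                              else 0
        dir <- dir / sqrt(sum(dir^2))
        cand <- ca[i - 1, ] + step * dir
        d <- sqrt(rowSums(sweep(prev, 2, cand)^2))
        if (i == 2L || all(d[-(i - 1L)] > 0.30)) break
      }
      ca[i, ] <- cand
    }

    resnames <- sample(.aa3, n_residues, replace = TRUE)
    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      n_sat <- sample(3:8, 1)
      sat_el <- sample(c("C", "N", "O", "H"), n_sat, replace = TRUE,
                       prob = c(0.45, 0.15, 0.15, 0.25))
      sat <- ca[rep(i, n_sat), , drop = FALSE] +
        t(vapply(runif(n_sat, 0.08, 0.22), function(r) r * .rand_unit(),
                 numeric(3)))
      el <- c("C", sat_el)
      rows[[i]] <- data.frame(
        residue = i, resname = resnames[i],
        name = c("CA", paste0(sat_el, seq_len(n_sat))),
        element = el, mass = element_mass(el), charge = 0,
        x = c(ca[i, 1], sat[, 1]), y = c(ca[i, 2], sat[, 2]),
        z = c(ca[i, 3], sat[, 3]),
        is_calpha = c(TRUE, rep(FALSE, n_sat)),
        stringsAsFactors = FALSE
      )
    }
    atoms <- do.call(rbind, rows)

    n_lig <- sample(5:20, 1)
    center <- ca[pocket, ] + runif(1, 0.25, 0.35) * .rand_unit()
    lxyz <- matrix(rep(center, each = n_lig), n_lig, 3) +
      t(vapply(runif(n_lig, 0, 0.12), function(r) r * .rand_unit(),
               numeric(3)))
    lig_el <- sample(c("C", "N", "O"), n_lig, replace = TRUE)
    q <- runif(n_lig, -0.3, 0.3)
    q <- q - mean(q)
    ligand <- data.frame(
      name = paste0(lig_el, seq_len(n_lig)), element = lig_el,
      mass = element_mass(lig_el), charge = q,
      x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
      resname = "LIG", stringsAsFactors = FALSE
    )

    # shift into positive octant and wrap a box around everything
    all_xyz <- rbind(as.matrix(atoms[, c("x", "y", "z")]),
                     as.matrix(ligand[, c("x", "y", "z")]))
    shift <- apply(all_xyz, 2, min) - 0.5
    for (k in 1:3) {
      col <- c("x", "y", "z")[k]
      atoms[[col]] <- atoms[[col]] - shift[k]
      ligand[[col]] <- ligand[[col]] - shift[k]
    }
    box <- apply(rbind(as.matrix(atoms[, c("x", "y", "z")]),
                       as.matrix(ligand[, c("x", "y", "z")])), 2, max) + 0.5

    drs_structure(atoms, ligand, box)
  })
}
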