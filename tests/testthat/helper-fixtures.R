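# shared fixture builders

# minimal structure whose residues are single non-amino pseudo-atoms at
# given positions (mapping-level tests that need exact centers of mass)
point_structure <- function(positions, ligand_xyz,
                            masses = rep(12.011, nrow(positions))) {
  n <- nrow(positions)
  atoms <- data.frame(
    residue = seq_len(n), resname = "UNK",
    name = paste0("X", seq_len(n)), element = "C",
    mass = masses, charge = 0,
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    is_calpha = FALSE
  )
  ligand <- data.frame(
    name = paste0("L", seq_len(nrow(ligand_xyz))), element = "C",
    mass = 12.011, charge = 0,
    x = ligand_xyz[, 1], y = ligand_xyz[, 2], z = ligand_xyz[, 3],
    resname = "LIG"
  )
  drs_structure(atoms, ligand, box = c(10, 10, 10))
}

# structure whose residues are bare C-alpha atoms at given positions
ca_structure <- function(positions, ligand_xyz = NULL) {
  n <- nrow(positions)
  atoms <- data.frame(
    residue = seq_len(n), resname = "ALA", name = "CA", element = "C",
    mass = 12.011, charge = 0,
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    is_calpha = TRUE
  )
  if (is.null(ligand_xyz)) {
    ligand <- data.frame(name = character(), element = character(),
                         mass = numeric(), charge = numeric(),
                         x = numeric(), y = numeric(), z = numeric(),
                         resname = character())
  } else {
    ligand <- data.frame(
      name = paste0("L", seq_len(nrow(ligand_xyz))), element = "C",
      mass = 12.011, charge = 0,
      x = ligand_xyz[, 1], y = ligand_xyz[, 2], z = ligand_xyz[, 3],
      resname = "LIG")
  }
  drs_structure(atoms, ligand, box = c(10, 10, 10))
}

# pairwise distances between rows of two matrices (test-side)
.cross_dist_test <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b),
            0))
}

# random rigid rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# test-side angle/dihedral oracles (independent of the package internals)
t_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
}
t_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  atan2(sum(cross(n1, b2) / sqrt(sum(b2^2)) * n2), sum(n1 * n2))
}

# a bent 6-atom anchor scaffold with no collinear triples
anchor_xyz <- function() {
  rbind(c(0.0, 0.6, 0.4),   # p3
        c(0.0, 0.5, 0.0),   # p2
        c(0.0, 0.0, 0.0),   # p1
        c(0.5, 0.0, 0.0),   # l1
        c(0.8, 0.4, 0.0),   # l2
        c(1.1, 0.4, 0.5))   # l3
}

# restraints whose reference values equal the scaffold's own geometry
anchor_restraints <- function(ks = c(4000, 400, 400, 400, 400, 400)) {
  xyz <- anchor_xyz()
  boresch_restraints(
    anchors = 1:6,
    r0 = sqrt(sum((xyz[3, ] - xyz[4, ])^2)),
    theta_a0 = t_angle(xyz[2, ], xyz[3, ], xyz[4, ]),
    theta_b0 = t_angle(xyz[3, ], xyz[4, ], xyz[5, ]),
    phi_a0 = t_dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]),
    phi_b0 = t_dihedral(xyz[2, ], xyz[3, ], xyz[4, ], xyz[5, ]),
    phi_c0 = t_dihedral(xyz[3, ], xyz[4, ], xyz[5, ], xyz[6, ]),
    k_r = ks[1], k_theta_a = ks[2], k_theta_b = ks[3],
    k_phi_a = ks[4], k_phi_b = ks[5], k_phi_c = ks[6])
}
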