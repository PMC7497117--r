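---
title: "Dual-resolution protein models and alchemical binding free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resolution protein models and alchemical binding free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualres)
```

## The model

`dualres` implements a fixed (non-adaptive) dual-resolution description of
a protein-ligand complex. The active site and the ligand keep atomistic
detail; every other residue is collapsed onto its C-alpha atom, and these
beads form an elastic network model (ENM) that preserves the large-scale
conformational fluctuations of the fold. The solvent does not see the CG
beads' chemistry at all: each bead repels solvent (and the atomistic
region) through a purely repulsive Weeks-Chandler-Andersen (WCA) core
whose diameter tracks the residue's size.

The three ingredients are:

1. **Mapping.** Residues are sorted by increasing distance between their
   center of mass and the closest ligand atom; the first `n_at` become the
   atomistic region. Residues in direct contact with the ligand
   (heavy-atom minimum distance at or below 0.45 nm by default) must be in
   that set — the package fails loudly if a requested `n_at` would exclude
   a contact residue, rather than silently producing a chemically broken
   active site. The contact criterion itself is a package choice: "direct
   contact" is a chemical notion (hydrogen bonds, hydrophobic contacts),
   and 0.45 nm is the conventional heavy-atom proxy; it is configurable.
   Ties in the distance ranking are broken by residue index, so mappings
   are deterministic and nested (`n_at` and `n_at + 1` differ by exactly
   one residue).

2. **Elastic network.** Bonded C-alpha pairs (consecutive along the
   chain) get a stiff spring `k_b` (default 5e4 kJ mol^-1 nm^-2)
   regardless of separation; all other pairs get `k_nb` (default 160)
   if and only if their *native* distance is below the cutoff `r_c`
   (default 1.2 nm). The energy convention is `k (r - r0)^2` per unordered
   pair — note the absent 1/2: the printed constants are twice the
   conventional half-k spring constants, and all machinery (Hessian,
   fluctuations, fitting) uses this convention consistently.

3. **Coupling.** Each CG bead carries a WCA diameter
   `sigma_i = Rg_i * c`, with `Rg_i` the residue's (all-atom, mass
   weighted) radius of gyration and `c` a single dimensionless factor for
   all amino acids (default 0.658, calibrated against bulk solvent
   density; `epsilon = 0.34` kJ/mol, the carbon value of common all-atom
   force fields). `calibrate_c()` is target-agnostic bisection: the user
   supplies the monotone observable (for instance the solvent density of a
   reference system as a function of `c`) and its target value. The WCA
   term also acts between CG beads and atomistic-region atoms — an
   assumption of this package, since only the ENM constrains the two
   regions otherwise; it prevents unphysical AT/CG overlap with minimal
   machinery. The solvent interaction site (oxygen vs molecular center of
   mass) is user-designated; for three-site waters the two choices are
   nearly indistinguishable.

## Fluctuations and ENM parameterization

The ENM is parameterized against a reference per-residue C-alpha RMSF
profile (typically from an all-atom simulation; the package reads any
two-column text profile). The predicted fluctuations come from the network
Hessian at the native state: each bond contributes `2k u u^T` to its 3x3
blocks (`u` the native bond direction), the equilibrium covariance is
`kB T` times the pseudo-inverse over non-rigid modes, and
`RMSF_i = sqrt(tr C_ii)`. Because equilibrium fluctuations of a harmonic
system are mass-independent, no bead masses enter. Modes with eigenvalue
below `1e-8` of the largest are treated as rigid-body motion; a
non-collinear connected network has exactly six. Finding *more* near-zero
modes means the network is mechanically under-constrained (for instance a
chain fragmented by an atomistic insertion with no cross-links within
`r_c`), and `rmsf_from_hessian()` refuses to pseudo-invert it rather than
report fluctuations of a floppy body.

`fit_knb()` minimizes the RMSF root-mean-square error over `k_nb` alone
(`k_b` and `r_c` fixed) by golden-section search on `log10 k_nb` over
[1e-1, 1e6] to a relative tolerance of 1e-3. The objective is smooth and,
on every fixture we generate, unimodal on that interval; searching in the
logarithm makes the bracket scale-free.

A caveat the tests make explicit: the Hessian route is the *harmonic*
fluctuation. At 298 K with `k_nb = 160` the bead excursions of a small
synthetic fold are a sizable fraction of the native bond lengths, and
exact Boltzmann sampling (Metropolis Monte Carlo) of the same network
deviates from the harmonic prediction by 10-30% at chain ends. This is a
property of the distance-spring potential, not an error in either route.
The quantitative Monte-Carlo cross-check therefore runs in the stiff
regime (`k_nb = 2000`), where amplitudes are small, the harmonic
approximation is controlled, and the two routes agree to within a few
percent; the soft regime is still covered by exact identities
(equipartition on single modes, `RMSF ~ k^-1/2` scaling).

## Alchemical machinery

The binding free energy is realized through a thermodynamic cycle, never
computed as a direct end-state difference:

* complex leg: restraints on -> Coulomb off -> Lennard-Jones off
  (`dG_restr_on,c + dG_coul,c + dG_LJ,c = dG_compl`);
* ligand solvation leg: Coulomb on <- Lennard-Jones on
  (`dG_coul,l + dG_LJ,l = dG_lig`);
* analytic release of the orientational restraints to standard state
  (`dG_r_off`);
* `dG_bind = dG_compl + dG_lig + dG_r_off`.

Each stochastic leg is a thermodynamic integration
`dG = integral of <dU/dlambda>` over [0, 1]. The mixed Hamiltonian is
`U_lambda = lambda U_A + (1 - lambda) U_B` with per-term flags; linearly
mixed terms have the exact derivative `U_A - U_B`, while soft-core terms
supply their own analytic derivative (validated against central
differences at 1e-6 relative in the tests).

Numerical choices:

* **Quadrature** is the trapezoidal rule; it is exact for integrands
  linear in lambda and standard for TI on grids of 5-21 points. Endpoint
  coverage (lambda = 0 and 1) is required unless the caller explicitly
  opts into integrating only the sampled range. Default per-leg counts
  are 11 (restraints), 15 (Coulomb, complex), 5 (LJ, complex), 5
  (Coulomb, ligand), 16 (LJ, ligand), evenly spaced with endpoints; an
  endpoint-free `{0.1, 0.3, 0.5, 0.7, 0.9}` grid is selectable for the
  5-point legs for users who prefer interior sampling with extrapolation.
* **Soft core.** The Beutler-style form with `alpha = 0.5`, `p = 1`
  softens the Lennard-Jones radius as
  `A = alpha sigma^6 (1 - lambda)^p + r^6`, staying finite at `r = 0` for
  any `lambda < 1` and collapsing to plain LJ exactly at `lambda = 1`.
  Coulomb decoupling uses plain linear scaling: the staging order (charges
  off while the LJ cores are intact, only then LJ off) means no charge
  ever acts between overlapping cores, so Coulombic soft-coring is
  unnecessary.
* **Electrostatics** use the reaction-field form with `eps_rf = 80` and a
  1.2 nm cutoff; the shift constant makes the pair energy vanish
  continuously at the cutoff.
* **Restraints** are the one-distance, two-angle, three-dihedral
  orientational set; dihedral deviations wrap to the smallest signed
  difference in `(-pi, pi]` (the standard convention; the choice only
  matters for deviations beyond 180 degrees, where any harmonic restraint
  is already dubious). Releasing the restraints to a standard-state
  volume of 1.661 nm^3 has the closed stiff-spring form implemented in
  `boresch_analytic()`; the tests confirm it against direct numerical
  integration of the six separable restrained coordinates to within 1%.
* **Uncertainties.** Per-lambda series are block-averaged into four
  contiguous blocks; the CI half-width is Student-t at 95%. Component
  uncertainties combine by *linear addition* along the cycle — the
  convention under which the benchmark tables are internally consistent —
  with quadrature summation available as an option.

## Sampling

`langevin_run()` integrates underdamped Langevin dynamics with the BAOAB
splitting (half kick, half drift, exact Ornstein-Uhlenbeck velocity
refresh, half drift, half kick). BAOAB was chosen for its superior
configurational accuracy at large friction — the package default is
`gamma = 15 ps^-1` with a 1 fs step at 298 K — and because it degrades
gracefully to velocity Verlet at `gamma = 0`, which is what the energy
conservation test exercises. Runs are exactly reproducible per seed, and
a non-finite energy aborts with the step index rather than sampling
garbage. No constraint algorithms are implemented: the systems the
sampler targets here (ENM beads, toy fluids, alchemical fixtures) have no
rigid bonds.

## Mapping quality

For each resolution the complex-leg components (Coulomb, Lennard-Jones,
restraint) are compared with the fully atomistic reference through the
quadratic deviation

`delta^2 = (dG_Coul - dG_Coul,ref)^2 + (dG_LJ - dG_LJ,ref)^2 + (dG_Restr - dG_Restr,ref)^2`

deliberately *unweighted* by the statistical uncertainties: the statistic
measures systematic displacement of the components, and weighting would
let a noisy resolution mask a real bias. Only the complex leg enters
because only it depends on the protein resolution. `resolution_scan()`
reports the profile and the argmin (ties to the smaller, cheaper count).
On the shipped lysozyme-chitotriose benchmark tables the optimum is six
atomistic residues — the full first contact shell — with
`delta^2 = 11.74 (kJ/mol)^2` against `448.62` for three residues, even
though the *total* binding free energy is flat across resolutions: the
total hides an error cancellation between components that the
per-component statistic exposes.

## The synthetic fixture generator

`make_toy_complex()` emulates the geometric features the machinery
depends on: a compact (centroid-biased, self-avoiding) C-alpha random
walk with consecutive spacing 0.38 nm +/- 10%, 3-8 satellite atoms per
residue, and a 5-20 atom ligand cluster within 0.5 nm of a designated
pocket residue, with small zero-sum partial charges on the ligand. The
compactness bias is deliberate: an unbiased random walk produces extended
chains whose elastic networks are mechanically floppy, while real
proteins — and these fixtures — yield exactly six rigid-body zero modes.
What the toys do *not* emulate: chemistry (no realistic bonding,
rotamers, or force-field terms), secondary structure, explicit solvent,
and realistic charge distributions. Tests passing on these fixtures
validate the *machinery* (geometry, bookkeeping, estimators, integrators)
at full fidelity, and say nothing about force-field accuracy on real
complexes.

Problem sizes throughout the test-suite and reproduction script were
chosen as the smallest that leave the stochastic checks statistically
sharp: 10-30 residue fixtures, 21-point lambda grids with 3e4-1e5 samples
per point, 6e5 Metropolis samples for the fluctuation cross-check.

## A worked example

```{r example, eval = FALSE}
s <- make_toy_complex(12, seed = 1)
mp <- select_atomistic(s, n_at = 4)
topo <- build_enm(s, mp)
coup <- assign_sigmas(s, mp)
rmsf <- rmsf_from_hessian(enm_hessian(topo))

# benchmark cycle and mapping scan from the shipped component tables
cycles <- setNames(lapply(3:10, hewl_cycle), 3:10)
scan <- resolution_scan(cycles, hewl_cycle(NA))
scan$optimal_n_at
```

## Known limitations

* Single-chain, single-model PDB input; no mmCIF, no crystallographic
  symmetry.
* The package does not attempt explicit-solvent molecular dynamics of
  real proteins; the sampler is for the package's own reduced and toy
  systems, and reproduction of the benchmark's simulated legs uses the
  published component tables as inputs.
* The analytic restraint-release formula is the stiff-spring limit; for
  soft restraints (`beta k r0^2` of order 1) use the numerical route the
  tests demonstrate.
* MBAR/BAR estimators, enhanced sampling, barostats and Ewald
  electrostatics are out of scope.
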