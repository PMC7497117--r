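# dualres

Binding free energies from dual-resolution protein models in R.

Computing a protein-ligand binding free energy with full atomistic detail
is expensive, yet most of a protein only matters through the collective
fluctuations it imposes on the active site. `dualres` implements the
alternative: keep the active site and the ligand atomistic, reduce every
other residue to a C-alpha bead in an elastic network model (ENM), couple
the beads to their surroundings through a purely repulsive
Weeks-Chandler-Andersen (WCA) core — and ask, quantitatively, *how many*
residues must stay atomistic.

The package is aimed at molecular modellers who want to build and
interrogate such models: it provides the mapping machinery, the ENM and
its parameterization, the lambda-dependent potentials and sampler for
alchemical work, the thermodynamic-cycle bookkeeping, and the
mapping-quality statistic that locates the optimal resolution.

## The science in brief

**Model.** Residues are ranked by the distance of their center of mass to
the closest ligand atom; the nearest `n_at` stay atomistic (always
including the direct-contact residues). The remainder becomes an ENM with
energy

    E = sum_{i<j} k_ij (r_ij - r0_ij)^2 * theta(r_c - r0_ij)

with a stiff backbone constant `k_b = 5e4 kJ/mol/nm^2` for
chain-consecutive beads and `k_nb = 160` (fit to a reference C-alpha RMSF
profile via the network Hessian) for all other pairs within
`r_c = 1.2 nm` of their native separation. Each CG bead carries a WCA
diameter `sigma_i = Rg_i * c` (`c = 0.658`, `epsilon = 0.34 kJ/mol`).

**Binding free energy.** `dG_bind = dG_compl + dG_lig + dG_r_off` via a
thermodynamic cycle: restrain the ligand (Boresch-style orientational
restraints), switch off Coulomb, then Lennard-Jones (soft-core,
`alpha = 0.5`, `p = 1`) in the complex; solvate the ligand; release the
restraints analytically to standard state. Every stochastic leg is a
thermodynamic integration `dG = int_0^1 <dU/dlambda> dlambda`
(trapezoidal quadrature, BAOAB Langevin sampling at 298 K with
`gamma = 15 ps^-1` and 1 fs steps, four-block Student-t 95% errors).

**Mapping quality.** Per resolution, the complex-leg components are
compared with the fully atomistic reference through the quadratic
deviation `delta^2 = delta_Coul^2 + delta_LJ^2 + delta_Restr^2`;
`resolution_scan()` reports the profile and its argmin.

## Worked example

The package ships the published component free energies of the hen
egg-white lysozyme / di-N-acetylchitotriose benchmark as plain-text
tables, and recomputes every derived number from them:

```r
library(dualres)

hewl_cycle(NA)   # fully atomistic reference cycle
#> binding cycle (decoupling), kJ/mol
#>   dg_restr_on_c       3.6 +/- 0.4
#>   dg_coul_c         145.2 +/- 3.5
#>   dg_lj_c            44.2 +/- 5.2
#>   dg_coul_l        -142.8 +/- 1.7
#>   dg_lj_l            -9.1 +/- 6.3
#>   dG_compl          193.0 +/- 9.1
#>   dG_lig           -151.9 +/- 8.0
#>   dG_r_off          -31.3 (analytic)
#>   dG_bind             9.8 +/- 17.1

cycles <- setNames(lapply(3:10, hewl_cycle), 3:10)
resolution_scan(cycles, hewl_cycle(NA))
#> mapping-quality scan (complex-leg deviation from fully atomistic)
#>  n_at delta_sq     delta
#>     3   448.62 21.180652
#>     4    47.65  6.902898
#>     5    60.46  7.775603
#>     6    11.74  3.426368
#>     7    36.09  6.007495
#>     8   128.04 11.315476
#>     9    42.70  6.534524
#>    10    37.13  6.093439
#> optimal atomistic residue count: 6
```

The scan says: the *total* binding free energy is flat across
resolutions (every row lands within its error bar of the reference
`9.8 +/- 17.1 kJ/mol`), but the components drift — and six atomistic
residues, the complete first contact shell, minimize that drift.

Building a model from a structure works on any single-chain PDB with a
flagged ligand, or on the built-in synthetic complexes:

```r
s <- make_toy_complex(12, seed = 1)    # or read_pdb("complex.pdb", "NAG")
mp <- select_atomistic(s, n_at = 4)
topo <- build_enm(s, mp)               # C-alpha elastic network
coup <- assign_sigmas(s, mp)           # WCA coupling table
rmsf_from_hessian(enm_hessian(topo))   # predicted C-alpha fluctuations
```

A thin command-line wrapper for shell pipelines lives at
`inst/scripts/dualres.R` (`build-model`, `fit-enm`, `run-ti`, `cycle`,
`map-scan`, YAML config with all defaults pre-filled).

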