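Package: dualres
Title: Dual-Resolution Protein Models and Alchemical Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dual-resolution models of protein-ligand complexes in
    which the active site is kept atomistic while the remainder of the
    protein is reduced to a C-alpha elastic network coupled to the solvent
    through a purely repulsive Weeks-Chandler-Andersen term. Provides
    distance-ranked selection of the atomistic region, elastic-network
    parameterization against reference C-alpha fluctuation profiles,
    lambda-dependent potentials (soft-core Lennard-Jones, reaction-field
    electrostatics, Boresch-style orientational restraints), a Langevin
    (BAOAB) sampler, thermodynamic integration with block-averaged
    uncertainties, assembly of the alchemical binding cycle, and a
    quadratic-deviation statistic that locates the optimal number of
    atomistic residues.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
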