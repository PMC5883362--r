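Package: retamd
Title: Temperature-Accelerated Molecular Dynamics with Adaptive
    Temperature and Soft Ratcheting for Ligand Surface Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator for temperature-accelerated molecular
    dynamics (TAMD) in which auxiliary targets for collective variables,
    thermostatted at an artificially high temperature, drag a ligand over
    free-energy barriers.  Implements the re-TAMD variant: the artificial
    thermal energy adapts to the smallest ligand-receptor distance and a
    soft-ratcheting Monte Carlo filter on collective-variable target moves
    keeps the ligand diffusing along the receptor surface instead of
    escaping to solvent.  Ships coupled underdamped (BAOAB) and overdamped
    (Euler-Maruyama) Langevin integrators, built-in analytic landscapes and
    coarse-grained receptor-ligand complexes for validation, and the
    companion trajectory-analysis pipeline: 4 Angstrom contact detection
    with polar/hydrophobic classification by partial charge, per-residue
    contact profiles and hot spots, per-frame site-contact fractions, and
    phi/psi dihedral distributions.  Structures and trajectories are read
    and written as PDB with sidecar tab-separated charge and time-series
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
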