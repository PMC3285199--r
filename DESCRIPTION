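Package: ffvalidate
Title: Validate Molecular Mechanics Force Fields Against NMR and Folding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Back-calculates backbone NMR observables (scalar couplings via
    Karplus relations, residual dipolar couplings with alignment-tensor
    fitting and Q factors, Lipari-Szabo-type order parameters from internal
    autocorrelation functions) from protein conformational ensembles, assigns
    conformational states with a dual-cutoff RMSD scheme to count folding and
    unfolding events, computes helix-coil melting curves, and aggregates the
    results into a simple 0-6 force-field score. Includes seeded synthetic
    generators (two-state kinetics, Zimm-Bragg helix-coil chains,
    diffusion-in-a-cone bond-vector motion, tensor-generated couplings) with
    known ground truth so every analysis stage can be verified without
    molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
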