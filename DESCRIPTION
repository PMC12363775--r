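Package: lipidlens
Title: Trajectory Analysis of Triglyceride Dynamics at Membrane Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing molecular-dynamics trajectories of
    triglyceride (TG) in protein-laden bilayers: bound/unbound state
    classification and dissociation-constant estimation from frame counts,
    spatially partitioned lateral diffusion coefficients from
    time-origin-averaged mean squared displacement, a per-residue logistic
    lipid-protein interaction score with all-atom to coarse-grained bead
    mapping, single-linkage detection of TG coalescence (oil-lens
    nucleation), and lumenal-domain tilt angles. Includes synthetic
    trajectory generators with known ground truth (Brownian dynamics with a
    slow-diffusion trap, two-state binding kinetics, a C11 toroid fixture)
    so every estimator is testable without running molecular dynamics, plus
    readers and writers for GRO, DCD and a plain-text columnar trajectory
    format, and a one-command analysis pipeline with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
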