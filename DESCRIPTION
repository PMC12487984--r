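Package: cglipid
Title: Bottom-Up Coarse-Grained Lipid Force Fields by Variational Force Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for developing solvent-free coarse-grained (CG) lipid
    force fields from pseudo-atomistic trajectories. Implements six-bead
    center-of-mass mapping of coordinates and forces, Boltzmann-inversion
    prior potentials (harmonic bonds and a Lennard-Jones-inspired r^-6
    repulsion), delta-force variational force matching into a trainable
    potential (a graph message-passing network or a pairwise B-spline
    baseline), solvent-free Langevin dynamics under NVT with periodic
    boundaries, and a membrane observable suite (radial distribution
    functions, z-density profiles, thickness maps, orientational order
    parameters, lateral mean square displacement and diffusion constants).
    A synthetic-data module generates bilayer fixtures with exact forces
    from a toy force field with known parameters so that the whole pipeline
    can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
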