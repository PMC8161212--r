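Package: porelab
Title: Coarse-Grained Hemichannel Pore Models and Langevin Permeation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds simplified connexin-hemichannel pore models (a fixed
    body-centred-cubic carbon lattice with a drilled cylindrical pore, charged
    rings, calcium-like particles and Lennard-Jones pore stretching), runs
    desk-scale Langevin dynamics of ions and a coarse dipolar solvent under a
    constant transmembrane electric field, and computes the standard trajectory
    statistics for channel permeation studies: permeation event counting and
    rates, AUC-normalised axial and radial density profiles, water survival
    probability, dipole orientation along the pore axis, dipole orientational
    relaxation, water-accessible effective diameters and direct-sum
    electrostatic slice maps. Includes generators for synthetic ground-truth
    trajectories and readers/writers for PDB, X-PLOR PSF, XYZ and DCD files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
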