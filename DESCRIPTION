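Package: toprna
Title: Topological Constraints on RNA 3D Structure by Coarse-Grained Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-beads-per-nucleotide coarse-grained model of RNA in which
    secondary-structure helices are semirigid, single strands are freely
    rotatable, and all nonbonded forces are purely steric. Temperature
    replica-exchange Langevin dynamics samples the conformations accessible to
    a fixed secondary structure, and analysis routines quantify interhelical
    Euler-angle coverage, mutual information between helix orientations,
    contact free energies, tertiary folding cooperativity, and the native-state
    specificity of best-packed conformers. Includes a dot-bracket parser with
    tRNA cloverleaf element labelling, secondary-structure variant editing
    (strand cuts, loop resizing, stem insertion), flat-bottom distance
    restraints, and generators for ideal A-form helices, an idealized L-shaped
    tRNA reference, and synthetic validation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
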