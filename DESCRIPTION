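Package: peeldom
Title: Hierarchical Decomposition of Protein Structures into Units and Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch decomposition of a protein chain into a three-level
    structural hierarchy: secondary structures, Protein Units (compact
    fragments of intermediate size obtained by recursively peeling a
    logistic contact-probability map), and alternative domain partitions
    assembled from those units.  Each partition is scored on a discrete
    1-5 quality scale, the set of acceptable alternatives yields an
    ambiguity index (an h-index over partition qualities) and junction
    statistics, and every unit or domain receives a knowledge-based
    pseudo-energy whose sequence-shuffled decoy Z-score is mapped through
    Chebyshev's inequality to an Autonomous Unit Likelihood.  Includes a
    generator of synthetic C-alpha globule-linker structures with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
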