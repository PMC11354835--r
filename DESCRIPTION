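Package: wingmorph
Title: Wing Geometric Morphometrics for Honey Bee Africanization Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics of honey bee (Apis
    mellifera) forewings for population identification and Africanization
    assessment. Reads tpsDig2-style TPS landmark files, performs generalized
    Procrustes superimposition with tangent-space projection, principal
    component and canonical variate ordination with pairwise Mahalanobis
    distances and permutation tests, linear discriminant classification
    against pure-subspecies reference groups with leave-one-out
    cross-validation, and UPGMA clustering of groups with Newick export.
    Includes a minimal mitochondrial haplotype assigner (global-alignment
    percent identity against a reference panel) and a seeded synthetic-data
    generator emulating a highland apiary survey, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    MASS,
    vegan,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
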