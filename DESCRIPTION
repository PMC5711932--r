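Package: camconverge
Title: Convergence Screens for CAM Evolution in Diel Transcriptomes and Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for convergent evolution between independently evolved
    crassulacean acid metabolism (CAM) lineages. The expression arm compares
    diel (24-h light/dark) transcript time-courses of ortholog groups across a
    eudicot CAM species, a monocot CAM species and a C3 species, estimating
    circular phase shifts, testing time-window abundance contrasts with
    Benjamini-Hochberg control, and applying a three-criterion classifier for
    convergent re-scheduling of expression. The sequence arm clusters proteins
    into tribes by Markov clustering of a similarity graph, screens
    species-labelled gene trees for CAM-convergence clades, calls shared
    derived residues against C3/C4 backgrounds, and counts convergent versus
    divergent substitutions under Fitch parsimony. Synthetic-data generators
    with planted truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
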