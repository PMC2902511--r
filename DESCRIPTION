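Package: aldhtools
Title: Classification, Motif and Transposon Analysis of Plant ALDH Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing aldehyde dehydrogenase (ALDH) gene
    superfamilies from protein and nucleotide sequence: percent-identity
    family/subfamily classification and systematic naming under the ALDH Gene
    Nomenclature Committee (AGNC) criteria, global affine-gap protein alignment
    and a minimal progressive multiple alignment, PROSITE-syntax active-site
    motif scanning with a residue-charge rule for NAD(+)/NADP(+) cofactor
    preference, neighbor-joining phylogenies with bootstrap support, and
    transposable-element structure detection (target-site duplications,
    terminal inverted repeats) with LTR-divergence insertion dating under a
    Jukes-Cantor correction. Includes a seeded synthetic-data generator that
    produces sequence families at controlled identity, planted motifs,
    sequences evolved on known trees, and LTR elements of known age for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
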