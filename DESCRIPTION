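Package: polyclonesmc
Title: Consensus Somatic Mutation Calling and Verification for Polyclonal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and verifying somatic single-nucleotide
    mutation (SSM) calls from matched target/reference sequencing of
    polyclonal bulk tissue, such as airway brushings. Implements multi-caller
    consensus intersection with Dice concordance and truth-set evaluation,
    annotation-track based confidence tiering, mutational burden normalised
    by callable genome (SMC power), intermutation distances for rainfall
    analysis, constrained selection of verification candidates, an amplicon
    variant-allele-frequency decision matrix with extrapolation to a
    genome-wide false-positive estimate, and an exact binomial model of the
    clonal detection limit. A synthetic clone-mixture data generator
    reproduces the statistical structure of polyclonal brush samples so the
    whole pipeline can be exercised and property-tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
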