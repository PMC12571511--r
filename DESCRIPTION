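Package: clonedecon
Title: Joint Clonal Deconvolution and Phylogeny Inference from Bulk DNA-Seq
    Guided by Single-Cell RNA Copy Numbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves multi-sample bulk DNA sequencing variant data (single
    nucleotide variants, allele-specific segmental copy numbers, and structural
    variant breakpoints) into integer clonal genotypes, a rooted binary clonal
    phylogeny under a loss-supported Dollo model, and per-sample clone mixture
    fractions, using clone-level copy numbers derived from single-cell RNA
    sequencing as a guide. The optimization alternates a continuous mixture
    step with integer linear programs solved through a bundled HiGHS bridge,
    and ships a ground-truth simulator, an exhaustive small-instance oracle,
    and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    clue,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
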