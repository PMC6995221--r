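Package: embryohap
Title: Trio-Based Haplotype Reconstruction and Carrier Diagnosis for
    Single-Cell Embryo Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs paternal and maternal haplotype inheritance in
    preimplantation embryos genotyped after whole-genome amplification.
    Genotypes from a father-mother-affected-child trio plus one or more
    embryos are phased by Mendelian segregation, embryo haplotypes are
    compared site-by-site against the phased reference child, and a
    two-state hidden Markov model smooths the noisy identical/different
    observations into contiguous haplotype blocks, absorbing allelic
    drop-out and amplification errors. Carrier status of a disease allele
    is called from the block inherited at the mutation locus, with
    recombination inside the locus reported as a no-call. Includes a
    family simulator with known ground truth, deterministic SVG figures
    of block inheritance, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
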