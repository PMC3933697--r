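Package: idrfunc
Title: Sequence Features of Intrinsically Disordered Regions for Protein
    Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts seven families of numeric descriptors from intrinsically
    disordered region (IDR) amino-acid sequences and their PSI-BLAST
    position-specific scoring matrices (chemical composition, amino-acid
    composition and occurrence, composition-transition-distribution descriptors
    over five physicochemical properties, adjacent and one-gap residue bigrams,
    and profile bigrams), and uses them to predict GO Slim functional terms of
    the parent proteins with one-vs-rest Gaussian naive Bayes classifiers.
    Includes 10-fold cross-validated confusion statistics, Matthews correlation
    coefficients, per-IDR precision-recall analysis over a probability grid,
    readers for FASTA and PSI-BLAST ASCII PSSM files, and a seeded synthetic
    dataset generator with term-linked compositional signals for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
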