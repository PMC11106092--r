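Package: mseMarkers
Title: Marker Peptide Selection and Identification from LC-MSE Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for discovering and identifying marker
    peptides from bottom-up proteomics data acquired with alternating low/high
    collision energy (MSE) instruments. The package turns mzML runs into a
    linked feature-intensity/feature-metadata pair of tables, selects
    class-discriminating features with partial least squares discriminant
    analysis (PLS-DA) and variable-importance-in-projection (VIP) scores, and
    identifies the selected features against a custom database built by
    in-silico tryptic digestion of user-supplied protein sequences, including
    heat-induced modifications such as lactulosyllysine, a/b/y fragment ions
    with neutral losses, and isotopologue-resolved (fine) isotope patterns.
    A synthetic MSE data generator with full ground truth supports validation
    of every stage. The proof-of-principle application is heat-induced change
    in milk proteins, but the machinery is generic over any protein FASTA and
    binary sample contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    mzR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse
biocViews: Proteomics, MassSpectrometry, FeatureExtraction, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
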