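Package: herbshotgun
Title: Shotgun Metabarcoding of Multi-Ingredient Herbal Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of the biological ingredients (prescribed herbs,
    substitutions, adulterants, fungal contaminants and impurities) in powdered
    multi-ingredient herbal medicines from shotgun sequencing reads. Implements
    the full desk-scale chain: quality trimming, k-mer enrichment of reads
    belonging to the ITS2, psbA-trnH, matK and rbcL barcode regions, greedy
    overlap-consensus assembly with 100%-identity de-duplication, motif- and
    primer-anchored barcode annotation with conserved-flank trimming, de novo
    two-parent chimera screening, greedy centroid OTU clustering, read mapping
    with depth/coverage QC and a coverage-evenness false-positive diagnostic,
    multi-marker taxonomic assignment and prescription-aware classification.
    Includes a synthetic shotgun-library generator (mixture proportions, DNA
    degradation, sequencing error, plastid copy weighting, fungal contaminants,
    chimeras) with a per-read truth table, so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
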