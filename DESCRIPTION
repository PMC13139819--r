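Package: allerprofile
Title: Comparative Allergen-Repertoire Analysis for Crustacean Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative immunoproteomic analysis of allergen
    repertoires across related species: band presence/absence profile
    similarity (Dice-type similarity index and Pearson/phi coefficient)
    with UPGMA dendrograms and Newick export; consensus-sequence calling
    from homolog alignments with BLOSUM62-based protein and IgE-epitope
    conservation scoring; immunoassay statistics (ELISA positivity
    cutoffs, sensitization rates, percent inhibition and dose-response
    summaries); transcript-abundance aggregation and heatmap
    normalization with ANOVA/Tukey significance coding; and seeded
    synthetic-data generators emulating gels, blots, plates and
    transcriptomes for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
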