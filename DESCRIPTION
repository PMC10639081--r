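Package: isomutsig
Title: Isogenic Mutation Calling, Mutational Spectra and Oxygen-Dependent
    Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for studying oxygen-dependent mutagenesis in
    mismatch-repair deficient cell lines. Calls mutations unique to one sample
    within an isogenic clone set from per-position allele-count tables with
    Fisher-score filtering and ancestral-clone threshold calibration; classifies
    single base substitutions (SBS96) and short indels (ID83) into COSMIC-style
    channels; fits spectra to reference signature sets by non-negative least
    squares with strict greedy signature removal; extracts de novo signatures by
    non-negative matrix factorisation; forms oxygen difference spectra and
    two-component decompositions; relates mutations to replication timing,
    replication fork directionality and transcription with strand-bias
    statistics; separates clonal from subclonal mutations by variant allele
    frequency clustering; and generates fully synthetic inputs with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
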