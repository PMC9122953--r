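Package: siderotrait
Title: Detection, Abundance, and Environmental Drivers of Siderophore
    Uptake Traits in Picocyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the prevalence and environmental drivers
    of siderophore-consuming picocyanobacteria from genomic and
    metagenomic data. Implements anchor-gene neighborhood calling of
    TonB-dependent siderophore transport clusters in (possibly
    incomplete) genomes, genome-completeness-corrected estimation of the
    population frequency of the uptake trait, a single-copy core-gene
    normalized metagenomic trait-fraction statistic, a variable
    importance pipeline combining principal component signal extraction,
    random forest regression in nested cross-validation and Boruta
    shadow-feature relevance testing, and beta regression of trait
    fractions on binned covariates with estimated marginal means.
    Includes synthetic-data generators with known ground truth so every
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    GenomicRanges,
    glmmTMB,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
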