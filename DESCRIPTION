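Package: ghostmap
Title: Allelic Heterogeneity, Ghost Associations and Field Selection at a
    Seed-Dormancy Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for dissecting allelic heterogeneity and
    'synthetic' (ghost) associations in genome-wide association studies of
    inbred plant populations, and for estimating selection on locus
    haplotypes from staged field-sampling designs.  Provides an EMMA-style
    mixed-model association scan with spectral REML, a pairwise pseudo-SNP
    (logical-OR) scan, a multi-locus mixed model with forced start marker
    and extended-BIC model selection, local/global variance decomposition,
    linkage-disequilibrium profiles, a partial Mantel test, and
    corrected-count fitness estimators for destructive seedling and soil
    sampling.  A synthetic-data generator emulating a structured population
    of inbred lines segregating multiple dormancy alleles at one locus makes
    the whole pipeline testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
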