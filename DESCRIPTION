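Package: snppanel
Title: Reduced SNP Panel Design and Validation for Multi-Breed Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs reduced SNP genotyping panels (liquid-capture / targeted
    genotyping chips) from multi-breed genotype data.  Candidate markers are
    ranked by breed-differentiation statistics (Wright's Fst, allele-frequency
    delta, Rosenberg's informativeness for assignment), merged under a
    hierarchical priority scheme, and thinned with a 50-kb window, minimum
    positional-variance (SD2) spacing rule with priority-ordered filling of
    empty windows.  Panels are validated with PLINK-style sliding-window
    runs-of-homozygosity (ROH) detection, top-1% ROH-island discovery with
    gene/QTL interval annotation, principal component analysis, p-distance
    matrices with neighbor-joining trees, and linkage-disequilibrium decay
    curves.  A deterministic Balding-Nichols simulator generates multi-breed
    genotypes with missingness and planted homozygous tracts so every analysis
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    cluster,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
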