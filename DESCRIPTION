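Package: binQTL
Title: Bin-Map Construction and QTL Mapping for Biparental RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing (GBS) based QTL mapping in
    recombinant inbred line (RIL) populations: parental-origin genotype
    encoding and quality control, sliding-window genotype smoothing with
    breakpoint detection and population-wide 100-kb bin-marker construction,
    Kosambi genetic-map estimation, composite interval mapping with
    permutation-derived LOD thresholds and 1.5-LOD support intervals,
    cross-environment QTL merging, mixed-model BLUEs with variance components
    and broad-sense heritability, and marker/expression association
    statistics. Includes a synthetic RIL population generator (meiosis-level
    gamete tracking under single-seed descent) so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    lme4,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
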