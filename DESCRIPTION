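Package: hapCanopy
Title: Haplotype-Based GWAS of Remote-Sensing Canopy Traits in MAGIC Populations
Version: 0.1.0
Authors@R:
    person("hapCanopy", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for haplotype-based quantitative trait locus (QTL) mapping of
    time-course canopy traits in multi-parental advanced generation inter-cross
    (MAGIC) populations. Extracts per-plot canopy height (by differencing a
    digital surface model against a pre-transplant baseline), vegetation
    fraction (Otsu thresholding of the CIELAB a* channel) and leaf colour (-a*)
    from orthomosaic/DSM rasters; runs a per-SNP Kruskal-Wallis scan over
    founder-haplotype classes with a two-year SNP selection rule and 2-Mb QTL
    merging; and characterises QTL phenology via haplotype-effect profiles,
    quadratic time-course fits, correlation-based hierarchical clustering,
    allele-class tests and cross-trait contrasts. A synthetic-data module
    (founder-mosaic genome simulator, trait generator with stage-specific QTL
    effects, and a plot-scene renderer) makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
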