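Package: waxmap
Title: GBS Genotyping, F2 QTL Mapping and Duplication Analysis for Outbred Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genotyping-by-sequencing (GBS) analysis of F2
    populations derived from crosses between heterozygous parents, aimed at
    mapping qualitative leaf-surface traits such as epicuticular wax in
    switchgrass. Converts per-sample allele read depths into the A/B/H/C/D
    genotype score alphabet, consolidates and groups cosegregating markers,
    partitions them into intercross (HH) and backcross-like (AH/HA) datasets
    with segregation-distortion filtering, builds centimorgan maps from
    recombination fractions, and runs Haley-Knott interval mapping and
    composite interval mapping with permutation-based LOD thresholds.
    Downstream modules prioritize candidate genes inside a QTL support
    interval by intersecting differential-expression, variant-impact, gene
    ontology and coverage-absence evidence; classify homoeologs and paralogs
    from protein hit tables via collinear-block chaining; and detect
    ecotype-specific presence/absence (deletion) hotspots from panel
    missingness in fixed genomic windows. A seeded synthetic-data generator
    produces every input the pipeline consumes, with planted truth records
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
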