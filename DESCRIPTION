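Package: hybridRI
Title: Reproductive Isolation Barriers and Hybrid Genotype-Class Assignment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies stage-specific reproductive isolation (RI) between a
    pair of plant species and their hybrid zone: co-occurrence style barrier
    indices for geography, flowering phenology and pollinator assemblages,
    ethological isolation and Bateman's floral-constancy index from pollinator
    foraging bouts, postzygotic isolation from hand-pollination fruit and seed
    set, and the sequential absolute/relative contribution cascade that
    combines ordered barriers into total RI. Also selects diagnostic loci
    (fixed differences, Hudson FST = 1) from parental genotypes and assigns
    individuals to the six canonical hybrid classes (P1, P2, F1, F2, BC1, BC2)
    with a per-locus genotype-frequency likelihood model. Synthetic-data
    generators with known ground truth emulate every input so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    geosphere,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: PopulationGenetics, SNP, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
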