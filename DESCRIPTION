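Package: herdstruct
Title: Population Structure Analysis of Dense SNP Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for population-structure analysis of diploid
    biallelic SNP genotypes sampled from many breeds or populations: a quality
    control cascade (per-breed call rate, monomorphism, exact Hardy-Weinberg
    tests with Storey q-values), diversity summaries and Weir-Cockerham
    F-statistics, linkage-disequilibrium r2 with distance decay, allele-sharing
    and Reynolds distances with neighbor-joining trees and bootstrap supports,
    principal component and between-breed principal component analysis, spatial
    PCA of breed allele frequencies on a Gabriel neighbor graph with Moran's I,
    and maximum-likelihood admixture inference by an expectation-maximization
    algorithm. Includes a Balding-Nichols genotype simulator emulating
    hierarchical breed structure, admixed breeds, SNP-chip ascertainment bias
    and spatial allele-frequency clines, so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'data-io.R'
    'synthetic.R'
    'qc.R'
    'fstats.R'
    'ld.R'
    'distances.R'
    'trees.R'
    'ordination.R'
    'spca.R'
    'admixture.R'
    'pipeline.R'
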