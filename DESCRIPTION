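Package: herddiv
Title: Pedigree and Genomic Diversity Analysis for Small Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterise the genetic background of small, partially
    genotyped livestock populations. Implements pedigree-based diversity
    metrics (Meuwissen-Luo inbreeding, relatedness, equivalent complete
    generations, pedigree completeness, generation intervals, realized
    effective population size, and effective numbers of founders and
    ancestors by marginal contributions), genomic inbreeding from the
    VanRaden genomic relationship matrix and from runs of homozygosity
    detected by a consecutive scan, selection-signature islands from runs of
    homozygosity and heterozygosity, historical effective population size
    from linkage-disequilibrium decay, and inbreeding-depression regression
    of growth traits on inbreeding. A gene-dropping and Wright-Fisher
    simulator generates pedigrees, genotypes and phenotypes with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'depression.R'
    'gene-origin.R'
    'grm.R'
    'herddiv-package.R'
    'io.R'
    'ldne.R'
    'pedigree-inbreeding.R'
    'pedigree-structure.R'
    'pipeline.R'
    'qc.R'
    'roh.R'
    'simulate.R'
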