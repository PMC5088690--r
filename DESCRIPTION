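Package: apydim
Title: Dimensionality of Genomic Information and the Algorithm for Proven and Young
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the effective dimensionality of genomic information in
    livestock populations and to exploit it for efficient genomic prediction. The
    package builds VanRaden genomic relationship matrices (GRM) and pedigree
    numerator relationship matrices, profiles GRM eigenvalue spectra and counts the
    largest eigenvalues explaining a given fraction of variation (a proxy for the
    number of independent chromosome segments), computes the sparse factored GRM
    inverse of the Algorithm for Proven and Young (APY) with core subsets sized from
    those counts, solves GBLUP and single-step GBLUP mixed model equations with
    either inverse, and estimates effective population size by log-log interpolation
    of eigenvalue counts against simulated reference curves. A forward-in-time
    population simulator with drift-generated linkage disequilibrium supplies fully
    reproducible test populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'apydim-package.R'
    'relmat.R'
    'apycore.R'
    'synthpop.R'
    'dimension.R'
    'evaluate.R'
    'pipeline.R'
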