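Package: nehist
Title: Historical Effective Population Size from SNP-Chip Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the decay of linkage disequilibrium (LD) with genetic
    distance and the trajectory of historical effective population size (Ne)
    from dense SNP-chip genotypes, using Sved's expectation for r-squared and
    the T = 1/(2c) generation mapping. Includes genotype quality control
    (call rate, minor allele frequency, Hardy-Weinberg, sex checks,
    identity-by-state duplicate detection), genomic diversity summaries
    (heterozygosity, genomic relationship matrix, inbreeding, multidimensional
    scaling), three physical-to-genetic map conversion methods (a constant
    genome-wide cM/Mb ratio, chromosome-specific ratios, and local-polynomial
    interpolation of a sparse linkage map), inverse-variance aggregation of
    per-chromosome estimates, a parametric-bootstrap comparison of map
    methods, and a Wright-Fisher forward simulator with recombination for
    generating test data with a known Ne trajectory.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
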