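Package: ailmap
Title: Founder-Line Genotyping and QTL Mapping for Deep Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates founder line-origin genotypes from low-coverage sequencing
    of deep advanced intercross lines (AIL) and maps quantitative trait loci
    across generations. Implements sliding-window beta-mixture segmentation of
    line-allele read fractions run bidirectionally at two window sizes, with
    1 Mb bin scoring, forward/reverse reconciliation and quality filtering;
    Haley-Knott regression genome scans with within-generation phenotype
    standardization, permutation and FDR significance thresholds; multi-QTL
    drop-one variance accounting with effect sizes on the grams scale; and a
    genotype information-content statistic. Includes a full AIL simulator
    (outbred founder lines, recombining pedigrees, additive/dominance
    phenotypes, Poisson read depth) so every stage can be validated against a
    known truth track.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
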