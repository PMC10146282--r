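Package: tetrazyg
Title: Meiotic Behavior of Allotetraploid Parents Inferred from Tetraploid
    Progeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study meiosis in doubled-diploid (allotetraploid)
    parents from genotyping data of their tetraploid sexual progeny
    ('tetrazygs'): mining taxon-diagnostic SNPs with the GST differentiation
    statistic, window-based ancestral dosage calling from diagnostic-allele
    read counts, inference and cleaning of diploid gamete phylogenomic
    structures, maximum-likelihood estimation of preferential chromosome
    pairing, parental heterozygosity restitution, chi-square tests of
    deviation from tetrasomic segregation with false discovery rate control,
    Kosambi genetic maps on physical marker order, Marey-map recombination
    profiles, principal-coordinate views of progeny structure,
    dose-phenotype association scans, and a synthetic allotetraploid meiosis
    simulator with full ground truth for validation.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
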