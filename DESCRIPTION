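Package: tetramap
Title: Recessive-Locus Fine Mapping in Autotetraploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-mapping toolkit for recessive loci in autotetraploid crops
    such as blackberry. Implements bulked-segregant allele-frequency window
    scans, family-based identity-by-descent homozygosity mapping with
    diagnostic-SNP breakpoint refinement, dominance-coded exact-test
    association scans with Bonferroni control, segregation and contingency
    statistics, and an autotetraploid meiosis and sequencing simulator
    (multisomic inheritance, double reduction, pooled-bulk read counts) so
    every mapping stage can be validated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
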