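Package: ssrpop
Title: Population Genetic Diversity Analysis for Codominant SSR Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the standard microsatellite (SSR) population-genetics
    workflow on diploid codominant genotypes: GenAlEx-dialect and long-format
    genotype input/output, per-population per-locus diversity indices (Na, Ne,
    Shannon I, Ho, He, unbiased He, fixation index F, percent polymorphic
    loci), hierarchical F-statistics (Fis, Fit, Fst) in the gene-diversity
    formulation with island-model gene-flow estimates (Nm), Nei's unbiased
    genetic distance between populations, UPGMA clustering with Newick export,
    a Balding-Nichols multipopulation genotype simulator for validation, and
    NDVI band arithmetic for associated vegetation survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
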