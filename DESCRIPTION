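Package: diallelQG
Title: Quantitative Genetics of Full Diallel Crosses Among Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of full diallel crosses among inbred
    lines, built around fertility-type count traits. Provides a seeded
    synthetic-data generator for complete diallels with maternal and
    paternal symbiont (Wolbachia) infection effects, an embedded causal
    variant and an expression mediator; restricted maximum likelihood
    (REML) estimation of the Cockerham-Weir bio-model partitioning
    phenotypic variance into female and male extranuclear, extranuclear
    interaction, nuclear and nuclear interaction components; fixed-effect
    adjustment of phenotypes for parental infection status; sex-ratio and
    inbreeding contrasts; genome-wide association on female line means
    with homozygous 0/1 genotypes; and linear causal mediation analysis
    (average causal mediation effect) of a variant effect through gene
    expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
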