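Package: saconflict
Title: Sexual Antagonism, Recombination Rate and Gene Duplication Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intralocus sexual conflict from
    sex-specific GWAS effect sizes and relating conflict intensity to
    recombination rate and gene duplication. Implements per-locus
    sexual-antagonism statistics (effect-size conversion, cross-sex
    effect-size ratio, a sexual antagonism index), inverse-variance
    weighted regressions of allele frequency on effect-size ratio
    (pooled, category-interaction and category-stratified models),
    conflict-intensity tertiles with Brown-Mood median tests, Levene's
    tests and post-hoc pairwise median tests against windowed
    recombination maps, paralogue-family construction from scored gene
    pairs with proportion and rank-sum tests, and a seeded synthetic-data
    generator emulating the structure of all required inputs so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
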