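Package: winqtl
Title: Window-Based Mapping of Loci from Deregressed Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide mapping of loci explaining variance in a
    quantitative trait from deregressed estimated breeding values of
    related animals. Provides a synthetic half-sib population generator,
    the sample and marker quality-control chain used in progeny-test
    genotyping studies, deregression of breeding values with information
    weights, a two-step weighted mixed-model association scan (REML
    variance components on a genomic relationship matrix, then per-SNP
    generalized least squares), smoothing of per-SNP variance explained
    in sliding genomic windows, Tukey-fence outlier-window locus calling,
    and interval overlap with annotation features. PLINK bed/bim/fam and
    BED input/output are supported.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
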