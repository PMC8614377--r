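Package: apisqg
Title: Quantitative Genetics of Honeybee Queen Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based quantitative-genetic analysis of honeybee
    (Apis mellifera) queen morphological and reproductive traits.
    Builds numerator relationship matrices under haplodiploid
    inheritance with drone-group pseudo-sires, validates them by
    Monte-Carlo gene dropping, fits univariate and bivariate REML
    animal models with a week-of-year fixed effect on dense matrices,
    and derives heritabilities and genetic/phenotypic correlations
    with delta-method standard errors.  Includes a synthetic
    breeding-population generator emulating a two-year queen-breeding
    design with maternal sister lines and isolated-station matings, so
    the full pipeline is testable without access to breeder records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
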