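Package: covqtl
Title: Bivariate Covariation QTL Mapping in Full-Sib Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps pleiotropic ("covariation") QTLs that shift the joint mean
    of a pair of quantitative traits in an outbred full-sib (F1) mapping
    population. At every marker of a dense linkage map a bivariate-normal
    model with genotype-class-specific mean vectors and a shared covariance
    matrix is compared against a single-mean null by a log-likelihood-ratio
    statistic; genome-wide significance is calibrated by permutation of
    phenotype rows. Includes derived stem traits (stemwood volume and
    biomass, leaf length/width ratio), genotype-stratified trait-pair
    summaries with polynomial trend fits, co-location reporting across trait
    pairs, and a synthetic full-sib population simulator with Haldane
    linkage, testcross (1:1) and intercross (1:2:1) markers and planted
    pleiotropic QTLs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
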