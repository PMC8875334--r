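Package: trophoquant
Title: Patch-Based Quantification of NRF2/KEAP1 Immunohistochemistry in
    Decidua Stratified by Trophoblast Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of bright-field immunohistochemistry
    (IHC) protein expression in decidual tissue sections. Serial sections
    stained for CK7 (trophoblast marker), NRF2 and KEAP1 are flat-field
    corrected, stitched, masked by regions of disinterest, separated into
    hematoxylin and DAB optical densities, tessellated into patches classified
    by trophoblast density band (maternal 0%, low >0-50%, high >50%), spatially
    aligned, and summarised as per-band gray-level intensities together with
    trophoblast counts and densities. Includes the accompanying statistical
    layer (robust outlier removal, Kruskal-Wallis with Dunn post hoc, one-way
    ANOVA with Tukey, site-adjusted linear models and linear mixed models with
    subject random intercepts) and a permutation-based gene-set enrichment
    statistic for NRF2 functional gene sets. Ships a synthetic slide-phantom
    and expression-matrix generator with full ground truth so the whole
    pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    lme4,
    emmeans,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
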