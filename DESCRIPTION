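Package: cadmrmc
Title: CAD Validation of Reader Findings and Multi-Reader Multi-Case
    AFROC Analysis for Automated Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for observer-performance studies of automated 3D breast
    ultrasound (ABUS) screening in which a computer-aided detection (CAD)
    system is used as an independent validator of radiologists' findings.
    Reader lesion markers are matched to CAD regions by a spherical-distance
    criterion, unvalidated findings are rejected and classified by cause and
    truth status, and the effect on reader performance is quantified with
    empirical AFROC figures of merit, proper binormal (PROPROC) ROC curve
    fits, partial AUC over a restricted false-positive-fraction interval,
    sensitivity at fixed specificity, and Dorfman-Berbaum-Metz jackknife
    pseudovalue ANOVA with the Hillis correction. A synthetic study
    generator emulates the full multi-reader multi-case design (case mix,
    BI-RADS-anchored 0-100 suspicion scores, CAD operating point) so the
    complete pipeline can be exercised and tested without image data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
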