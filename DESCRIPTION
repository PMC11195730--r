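Package: dlzscore
Title: Device-Landing-Zone Calcium Quantification for Contrast Cardiac CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies aortic-root device-landing-zone (DLZ) calcification on
    contrast-enhanced cardiac CT for transcatheter aortic valve replacement
    (TAVR) planning. Detects calcium by false-positive-rate minimizing
    threshold selection against the contrast-filled lumen, maps calcific
    voxels into a patient-invariant 18-region cylindrical (bullseye) scheme
    normalized by aortic-root dimensions (annular radius, sinotubular-junction
    height, inter-commissure angles), and produces intensity-weighted regional
    volume scores per cusp. Includes device-relative metrics (area cover
    index, expansion deviation), the standard Agatston score for non-contrast
    CT, a nested multinomial logistic-regression evaluation harness with
    likelihood-ratio tests, one-vs-control ROC analysis with Youden cutoffs,
    and ICC agreement, plus synthetic phantom volumes and simulated cohorts
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
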