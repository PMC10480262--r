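Package: brachyrobust
Title: Robust Evaluation of HDR Prostate Brachytherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the robustness of high-dose-rate (HDR) prostate
    brachytherapy treatment plans to the combined effect of treatment
    uncertainties.  A nominal plan (needle dwell positions and times plus
    contoured prostate, urethra and rectum) is perturbed by six uncertainty
    operators: dwell shifts along the needle, prostate boundary
    expansion/contraction, slice-wise organ-at-risk contour scaling,
    transverse needle displacement, dwell-time scale/offset, and rigid
    prostate motion.  Dose is recomputed with the TG-43 formalism for
    probabilistic scenarios (truncated-normal sampling within a 90 percent
    confidence interval) and for an enumerated set of worst-case scenarios,
    and the resulting dose-volume histogram metrics are summarised with
    confidence intervals, skewness, bootstrap percentile intervals,
    constraint pass rates and a whole-curve standard-deviation-per-dose
    robustness area.  Includes a deterministic synthetic phantom emulating
    a typical ultrasound-planned case so the full pipeline runs without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    mgcv,
    e1071,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
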