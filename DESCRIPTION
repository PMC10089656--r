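Package: csfield
Title: Contrast Sensitivity Across and Around the Visual Field
Version: 0.1.0
Authors@R:
    person("csfield", "developers", email = "csfield@example.org", role = c("aut", "cre"))
Description: Tools for measuring and modelling the contrast sensitivity
    function (CSF) at multiple visual-field locations. Implements
    meridian-specific linear cortical magnification and M-scaling of
    stimulus size; a fixed-slope logistic contrast-response function with
    exact threshold targeting; nine parametric CSF forms with attribute
    extraction (peak sensitivity, peak and cutoff spatial frequency,
    area under the log CSF, bandwidth); trial-wise Bernoulli maximum
    likelihood fitting of CSFs jointly across eccentricity and polar
    angle under a family of parameter-tying models compared by BIC;
    adaptive contrast titration (best PEST and a weighted 3-down-1-up
    staircase targeting 75 percent correct); a synthetic observer and
    experiment simulator with configurable eccentricity effects and
    polar-angle asymmetries; and quantification of those asymmetries
    with repeated-measures ANOVA, post hoc t-tests, bootstrap
    confidence intervals, and rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
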