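Package: tunlsim
Title: Simulation and Analysis of the Trial-Unique Nonmatching-to-Location
    Touchscreen Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A discrete-event simulator and analysis toolkit for the
    trial-unique nonmatching-to-location (TUNL) touchscreen task for rodents.
    Implements the mask geometry and separation metrics, the full trial state
    machine with correction trials and session caps, pre-training stages,
    counterbalanced experiment schedulers, parametric subject agents whose
    accuracy depends on delay, spatial separation and hippocampal-lesion
    status, and the analysis layer: percent correct excluding correction
    trials, chance tests, and the per-rat mediating-behavior benefit score
    with Bonferroni-corrected t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
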