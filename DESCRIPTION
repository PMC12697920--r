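Package: actisleep
Title: Actigraphy Sleep-Wake Scoring Algorithms and Polysomnography
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements five classical weighted-window actigraphy sleep-wake
    scoring algorithms (Cole-Kripke, UCSD, Kripke 2010, Philips-Respironics
    at three wake thresholds, and Sadeh), Webster's five rescoring rules,
    30-second to 1-minute epoch harmonization with the wake-wins rule for
    polysomnography labels, and derivation of total sleep time, sleep
    efficiency and wake after sleep onset.  Provides the full
    agreement-statistics suite used to validate actigraphy against
    polysomnography: epoch-by-epoch confusion metrics, Cohen's kappa,
    Matthews correlation coefficient, ROC/AUC, Bland-Altman limits of
    agreement with proportional bias, one-way repeated-measures ANOVA with
    Mauchly's test and Greenhouse-Geisser correction, Bonferroni post hocs
    with Hedges' g, and a two-tier outlier sensitivity analysis.  Includes a
    synthetic paired-night generator emulating single-night community
    actigraphy/polysomnography recordings so the whole pipeline is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
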