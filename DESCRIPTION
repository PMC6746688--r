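Package: photanthro
Title: Landmark-Based Indirect Breast Anthropometry from Calibrated Photographs
Version: 1.0.0
Authors@R: person("photanthro", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Linear breast measurements from 2-D clinical photographs using
    named anatomical landmarks and an in-frame reference segment of known
    length for pixel-to-centimetre calibration. Implements midline
    construction from sternal notch and umbilicus, level differences by
    orthogonal projection onto the midline, two-photo similarity binding for
    ptotic subjects, the 13-measurement clinical panel with 45:55 and 40:60
    aesthetic ratios, and the full reliability battery used to validate such
    tools: mean absolute difference, intraclass correlation coefficients with
    F-based 95% confidence intervals, standard error of measurement,
    coefficients of variation, Bland-Altman limits of agreement, and ICC
    interpretation bands. A synthetic-subject generator with photo framing
    and observer noise models makes the whole pipeline testable without
    human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
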