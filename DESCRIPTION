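Package: rrsat
Title: Resource-Rational Speed-Accuracy Trade-Offs in Perceptual Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the trade-off between judgment accuracy and
    thinking costs in simple perceptual binary-choice tasks. Implements a
    Metropolis-Hastings anchoring-and-adjustment simulator with a linear
    thinking-cost schedule and total-benefit peak-time statistics, a
    mouse-tracking measurement pipeline (time-normalized trajectory area
    under the curve, response-time-category accuracy, cumulative
    response-time distributions, irritation scoring, nonparametric effect
    sizes), and a synthetic-data generator that emulates a three-group
    waiting-time experiment so the whole pipeline can be exercised without
    participant data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
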