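Package: enzisfet
Title: Enzyme-ISFET Carbaryl Quantification with Neural Signal Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the carbamate pesticide carbaryl from
    acetylcholinesterase-inhibition ISFET biosensor readings taken at
    arbitrary solution temperatures (20-35 degrees Celsius). Implements a
    from-scratch feed-forward regression network (tanh hidden layers, ReLU
    output, full-batch gradient descent) mapping the gate-source signal
    response and solution temperature to concentration, a single-input
    companion network that models the temperature dependence of the
    no-pesticide reference signal for per-sensor calibration, a
    vegetable-extract matrix correction, enzyme-inhibition and
    3-sigma limit-of-detection arithmetic, and a parametric simulator of
    enzyme-ISFET responses so the whole pipeline is buildable and testable
    without hardware.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
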