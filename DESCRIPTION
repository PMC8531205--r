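Package: tadscope
Title: Thermal Physiology Pipelines for Tadpole Acclimation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipelines for comparative thermal ecophysiology of
    aquatic ectotherms. Converts intermittent-flow respirometry traces
    (percent air saturation) into quality-controlled routine and maximum
    metabolic rates via a freshwater oxygen-solubility model and the
    effective-volume equation; detects heartbeats in raw electrode
    recordings and partitions cholinergic and adrenergic tones from
    atropine/sotalol blockade designs; extracts critical thermal maxima
    and warming tolerance from heating ramps; summarizes microhabitat
    temperature-logger series; and combines metabolic rates into aerobic
    scope and Gaussian thermal performance curves with Q10 temperature
    coefficients. A synthetic-data module generates every raw input type
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
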