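Package: vcdvalue
Title: Decision-Analytic Cost-Effectiveness Modeling of Vascular Closure
    Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic decision-tree model of hemostasis strategies after
    transfemoral cardiac catheterization (manual compression versus vascular
    closure devices, plus hypothetical bleeding-preventing device variants)
    from the perspective of the German Statutory Health Insurance. Computes
    expected complications and costs per catheterization with DRG
    difference costing, incremental cost-effectiveness ratios with dominance
    classification, per-complication cost savings, effectiveness sweeps,
    one-way deterministic sensitivity analysis with tornado ordering, and
    value-based pricing (cost-saving premium, efficiency-frontier premium,
    same-day-discharge savings). Ships the published model parameterization
    as a fixture and a synthetic parameter generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
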