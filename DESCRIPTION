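Package: baroloop
Title: Equilibrium-Diagram Analysis of Sympathetic Arterial Baroreflex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Static closed-loop analysis of sympathetic arterial baroreflex
    function on the plasma-norepinephrine versus arterial-pressure plane.
    Models the mechanoneural (baroreceptor-to-sympathetic) and
    neuromechanical (sympathetic-to-pressure) arcs as intersecting
    functional curves, solves the closed-loop operating point, computes
    open-loop gain and disturbance attenuation, and decomposes the
    pressure response to head-up tilt into closed-loop and open-loop
    components. Includes the estimation pipeline for tilt plus
    ganglionic-blockade study tables (per-subject arc regressions,
    two-point neuromechanical fits, exact Wilcoxon signed-rank
    comparisons), a seeded synthetic tilt-study generator for end-to-end
    testing, and a command-line pipeline with delimited-table and JSON
    report schemas.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
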