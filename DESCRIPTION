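Package: bladeforge
Title: Surrogate-Assisted Inverse Design of Axial Blood-Pump Blades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Inverse-design workflow for the blades of miniature axial-flow
    left ventricular assist devices. Parameterises circular-arc impeller and
    diffuser blades by five governing parameters, evaluates designs with an
    affinity-exact analytic mean-line pump model, scales pressure-flow and
    efficiency-flow curves to a clinical operating point through turbomachinery
    similitude laws, trains multi-linear, Gaussian-process and
    Bayesian-regularised neural-network surrogates of design-point efficiency,
    and searches the design space with a constrained real-coded genetic
    algorithm under iteratively widened bounds. Tibble-first interfaces with
    broom-style tidiers and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
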