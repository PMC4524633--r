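Package: ceradyn
Title: Dynamic Flux and Enzyme-Activity Inference for the Yeast Ceramide Subsystem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts short metabolic time series of dihydro- and phytoceramide
    species in heat-stressed Saccharomyces cerevisiae into time-varying enzyme
    activity trends. Implements a Generalized Mass Action (GMA) model of
    ceramide biosynthesis, utilization, hydroxylation, IPC exchange and
    fatty-acyl elongation (15 metabolite pools, 53 fluxes), smoothing-spline
    preprocessing with per-minute resampling, per-minute dynamic flux
    estimation by ensembles of bound-constrained least-squares solves from
    random restarts, activity proxies (Vmax-like rate-constant x enzyme
    activity products), and a multiple-shooting style refinement of windowed
    activity coefficients against the concentration data. A synthetic-data
    generator produces ground-truth heat-stress scenarios so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
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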