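Package: hscsoma
Title: Stochastic Simulation of Somatic Evolution in Hematopoietic Stem-Cell Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Monte Carlo model of a human hematopoietic stem-cell
    (HSC) pool across an 85-year lifespan. Cells divide on a weekly clock with
    age-dependent division rates, draw net fitness effects from a configurable
    distribution of fitness effects (DFE) with asymmetric tails and a
    time-ramped mutation rate, accumulate neutral Tier-3 passenger mutations,
    and compete for an age-dependent niche carrying capacity through a
    fitness-weighted survival lottery. An optional bicomponent microenvironment
    model imposes a logistic age-dependent mean-fitness decline plus
    distributed per-cell perturbations. Includes metrics (Tier-3
    mutation-accumulation slope, largest-clone expansion, shape similarity of
    clonal-expansion trajectories to a leukemia-incidence reference curve),
    parameter-sweep machinery over DFE variance and mutation-rate fold
    increase with plausible-range and overlap statistics, and a numeric
    multistage driver-probability integral.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
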