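Package: childmort
Title: Bayesian Estimation and Scenario Projection of Under-5, Infant, and
    Neonatal Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits bias-adjusted Bayesian penalized B-spline trends to
    heterogeneous country-level child-mortality observations (vital
    registration, sample registration, full and summary birth histories,
    censuses), derives neonatal mortality through an expected-ratio model
    with country-specific multipliers, converts rate trajectories and live
    births into death counts using 52 weekly birth cohorts, computes
    annual-rate-of-reduction metrics with posterior uncertainty, and
    projects mortality and deaths for 2025-2030 under constant, current
    trends, SDG-target, and high-income scenarios.  Includes a synthetic
    data generator emulating the multi-series, multi-source error structure
    of the international child-mortality database so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: splines, stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
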