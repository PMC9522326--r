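Package: polyconform
Title: Conformity and Anticonformity Dynamics for Polychotomous Cultural Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic frequency dynamics for a discrete, selectively
    neutral cultural trait with m variants transmitted by samples of n role
    models under frequency-dependent (conformist or anticonformist) bias.
    Provides exact one-generation recursions on the frequency simplex via
    full enumeration of multinomial role-model configurations, flexible
    per-configuration conformity-coefficient schemes with admissibility
    bounds, equilibrium catalogues with analytic and numerical (Jacobian)
    local-stability verdicts, and long-run trajectory classification into
    fixed points, exact period-k cycles, or sustained aperiodic (chaotic)
    fluctuation with a divergence-rate diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
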