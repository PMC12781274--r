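Package: carbodyn
Title: Coupled Dynamics of Atmospheric CO2, GDP, Forest Area and Human Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-compartment nonlinear ordinary differential
    equation model coupling atmospheric carbon dioxide concentration, gross
    domestic product, forest area and human population. Provides the vector
    field and Jacobian, trajectory integration, the invariant bounding region,
    closed-form boundary equilibria and the interior equilibrium by nullcline
    root finding, Routh-Hurwitz and eigenvalue local stability analysis, a
    Lyapunov-function global stability check, Latin hypercube sampling with
    partial rank correlation coefficient (PRCC) sensitivity analysis, a
    Pontryagin optimal-control solver using the forward-backward sweep method,
    and a synthetic annual-observation generator with simple rate estimators
    and least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
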