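Package: parastab
Title: Stability Analysis of Generalized Host-Parasitoid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing stabilizing mechanisms in continuous-time
    (generalized Lotka-Volterra) and discrete-time (semi-discretely derived,
    generalized Nicholson-Bailey) host-parasitoid models with density-dependent
    parasitoid attack rates. Provides attack-rate families (Type II, generalized
    Hill/Type III, parasitoid-dependent power laws, monomials) and their
    dimensionless log sensitivities, nontrivial equilibria, Jacobians, analytic
    stability criteria (Hurwitz trace/determinant and Jury conditions),
    trajectory simulation via adaptive ODE integration and map iteration, and
    stability-region atlases over the plane of attack-rate log sensitivities,
    including boundary curves, corner points and asymptotic limits in host
    reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
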