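Package: cortcond
Title: Growth-Law Analysis of Short-Lived Cortical Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct mass-flux phase portraits from tracked
    WSP-1/F-actin cortical condensate intensity time series, fit the empirical
    mass-action growth laws that govern condensate assembly and disassembly,
    and analyse the fitted dynamical system (nullclines, dominant composition,
    critical point separating bounded grow-and-dissolve cycles from unbounded
    growth). Includes a stochastic track-ensemble generator that emulates the
    observation process (Poisson nucleation, intrinsic rate noise,
    multiplicative measurement noise, detection truncation) so that every
    analysis stage is testable without microscopy data, plus volume-relation
    fitting, concentration analysis, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
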