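Package: odegraph
Title: Build, Simulate and Export ODE Models as Dataflow Node Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construct ordinary differential equation (ODE) models as typed
    node graphs of Terms (variables, parameters, constants), Expressions
    (arithmetic or user-defined operators) and Assigners (one per ODE
    right-hand side). Models serialize to a documented JSON intermediate
    representation, simulate in-process with adaptive Runge-Kutta
    integration (via 'deSolve'), and export as standalone, runnable R
    scripts produced by template-based code generation. The node vocabulary
    is extensible through plugin files of decorated functions. Ships
    programmatic builders for classic and extended SIR epidemic models, a
    simplified immune-regulation model and the Lotka-Volterra predator-prey
    model, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
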