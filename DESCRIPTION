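Package: identicombo
Title: Structural Identifiability Analysis and Identifiable Parameter
    Combinations for Rational ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides which parameters of a rational-function ODE
    system-experiment model are uniquely, locally (with a maximum solution
    count) or not structurally identifiable from stated input-output data,
    and, for unidentifiable models, computes explicit structurally
    identifiable parameter combinations. Models are entered in a plain-text
    compartmental-modelling syntax with optional known initial conditions.
    The method eliminates states by differential algebra to obtain the
    input-output equations, extracts their normalized coefficients as an
    exhaustive summary, and analyses the fiber of the coefficient map at a
    pseudo-random parameter point with Groebner bases over a sequence of
    lexicographic parameter orderings; binomial and decoupled basis elements
    yield simple identifiable combinations. Includes an exact symbolic
    kernel (arbitrary-precision rational and modular multivariate polynomial
    arithmetic, Buchberger's algorithm) implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
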