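Package: fertresp
Title: Fertilizer Response Modelling for "3414" Rice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and compares two yield response surfaces to "3414"-design
    N-P2O5-K2O fertilizer trials in paddy rice: the ternary non-structural
    model Y = A(N0+N)(P0+P)(K0+K)exp(-c1 N - c2 P - c3 K), estimated by
    multi-start nonlinear least squares, and the classical ternary quadratic
    polynomial, estimated by ordinary least squares. Provides significance
    testing, typicality classification of fitted surfaces (coefficient
    signs, existence of a global maximum via Hessian principal minors,
    recommendations inside the design range), maximum-yield and economic
    fertilization recommendations by the marginal product derivative
    method, synthetic trial generation for parameter-recovery experiments,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
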