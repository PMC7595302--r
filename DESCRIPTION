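Package: kernsens
Title: Analytic Derivatives and Sensitivity Analysis for Kernel Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic first, second and higher-order derivatives of the common
    kernel functions (linear, polynomial, RBF, hyperbolic tangent, ARD) and of
    arbitrary kernel expansions f(x) = sum_i alpha_i k(x, x_i), together with
    the derivative-based analyses they enable: feature and point sensitivity
    maps for Gaussian process / kernel ridge regression, masked decision-
    function gradients for support vector machine classification, density
    ridge (principal curve) point extraction for Parzen and kernel entropy
    component density estimates, and derivative fields and gradient flows for
    the Hilbert-Schmidt Independence Criterion. Includes seeded synthetic data
    generators for all built-in experiments and a finite-difference oracle for
    derivative checking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    kernlab,
    igraph,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
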