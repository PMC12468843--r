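Package: ineqtree
Title: Localization of Inequality in Probability Distributions via
    Recursive Entropy-Based Hahn Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies and localizes inequality in discrete and continuous
    probability distributions using the degree of uniformity, the exponential
    of Shannon entropy (Hill number of order one) per unit probability mass.
    A signed measure built from this quantity admits an explicit ternary Hahn
    decomposition of any measurable part into strictly positive, null and
    strictly negative pieces; applying it recursively yields a ternary
    localization tree whose levels order parts by strictly decreasing degree
    of uniformity. Includes closed-form support for exponential and
    piecewise-constant densities, level-set root finding on declared monotone
    segments, a brute-force maximality oracle, designed null-set
    construction, histogram and density readers, synthetic fixture
    generators, JSON tree export and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
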