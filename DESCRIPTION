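Package: osmodry
Title: Response Analysis and Optimization of Osmotic Dehydration Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing osmotic dehydration experiments laid out as
    three-factor Box-Behnken designs. Computes the dehydration response
    indices (dry matter content, water loss, solid gain) from mass balances,
    ranks experimental runs by a multi-criteria standard score built from
    min-max normalized responses, characterizes the response set by Pearson
    correlation, complete-linkage city-block clustering and correlation-matrix
    principal component analysis, fits small multilayer-perceptron response
    models by BFGS with restarts and topology search, derives signed relative
    importance of the process factors from the trained connection weights
    (Yoon's method), and evaluates model fit with a suite of goodness-of-fit
    metrics and residual moments. Ships the run table of a published
    beetroot-in-molasses dehydration study as a plain-text fixture and a
    generator of synthetic Box-Behnken tables from known quadratic response
    surfaces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
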