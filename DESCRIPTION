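Package: flavorsim
Title: Population Health Impact of Prohibiting Characterizing Flavors in Cigars
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A decision-analytic simulation of the public health benefits of a
    nationwide prohibition of characterizing flavors in cigars. Implements two
    static model chains -- premature deaths avoided per year among current
    exclusive cigar smokers through increased cessation, and cigar users
    prevented in a cohort of 18 year olds through deterred initiation and
    reduced continuation -- with deterministic point estimates, seeded Monte
    Carlo uncertainty propagation over triangular input distributions,
    quantile-based prediction intervals, and one-way (tornado) sensitivity
    analysis by conditional output means over equal-probability input bins.
    Ships scenario configuration I/O, report generation, and a synthetic
    scenario generator with closed-form expected outputs for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
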