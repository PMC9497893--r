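Package: kpconv
Title: Interleaved Grouped Pointwise Convolutions for Parameter-Efficient CNNs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and builds two-layer grouped pointwise convolution
    subnetworks (a grouped layer K, a channel interleaving, a grouped layer L
    and a residual sum) that replace standard 1x1 convolutions in
    convolutional image classifiers without divisibility constraints between
    channel counts and group widths.  Non-divisible configurations are
    handled by replicating leading input channels and by adding a second
    one-filter-per-group path.  Includes exact trainable-parameter and
    multiply-accumulate accounting, a declarative EfficientNet-B0 backbone
    with wholesale substitution of eligible pointwise layers, a brute-force
    convolution oracle for equivalence testing, synthetic image fixtures,
    horizontal-flip ensemble inference and a smoke-training loop, all on
    plain numeric arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
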