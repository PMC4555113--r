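Package: bowfood
Title: Bag-of-Visual-Words Recognition of Food Record Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated recognition of food items in food-record photographs
    using a bag-of-visual-words model. Images are described through three
    local feature channels (gradient-orientation shape descriptors, uniform
    local binary pattern texture histograms, and quantized RGB colour
    histograms) extracted at difference-of-Gaussian interest points,
    vector-quantized against per-channel codebooks learned by chi-squared
    K-means, and classified by one-vs-rest linear support vector machines.
    Supports single-label prediction, sensitivity-thresholded multi-label
    prediction, Jaccard-index evaluation with a per-category threshold
    sweep, feature-channel ablation, and a fully reproducible synthetic
    food-image generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
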