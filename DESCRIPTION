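Package: bpregress
Title: Self-Supervised Body Part Regression for Axial Medical Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised body part regression (BPR) for axial CT-like
    volumes: a slice-scoring network trained with ranking losses (an order
    loss on consecutive slice-score differences and a smooth-L1 distance
    loss on differences of consecutive score gaps) over random equidistant
    slice stacks, so that every axial slice is mapped to a continuous score
    encoding its inferior-to-superior position without any labels. Includes
    score post-processing (Gaussian smoothing, landmark-anchored
    normalization to a 0-100 scale), organ-landmark calibration tables,
    landmark-slice prediction with rescaled mean absolute error, paired
    model comparison with Bonferroni-corrected Wilcoxon tests, score-driven
    anatomical region cropping for localized segmentation, Dice utilities,
    a Monte-Carlo/exact analysis of the slice sampler's coverage, and a
    procedural CT-phantom generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
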