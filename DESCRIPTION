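Package: antl
Title: Adaptive Neighborhood Triplet Loss for Binary Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the adaptive neighborhood triplet loss (ANTL) for
    two-class per-pixel segmentation. The loss mines, within each labeled
    region, the k best-predicted pixels and k relatively hard-to-predict
    pixels (own-class probability inside an adaptively widened search
    interval starting at (0.5, 0.55)), expands the hard pixels into layered
    8-connected same-label neighborhoods, and penalizes triplets formed from
    the best pixels (anchors), the same-class hard neighborhoods (positives)
    and the other-class hard neighborhoods (negatives). Includes the
    composite objective combining ANTL with binary cross-entropy, gradient
    machinery with a finite-difference check, a synthetic generator of
    blob-shaped masks and boundary-degraded probability maps, a desk-scale
    logistic segmentation demo, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
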