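Package: histannot
Title: Active-Learning Annotation Engine for Histologic Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless engine for rapid annotation of histologic structures in
    digital pathology image tiles. A compact encoder-decoder segmentation
    network is pretrained unsupervised as an autoencoder on image patches,
    fine-tuned on sparse three-class (positive/negative/unknown) annotation
    masks, and improved iteratively by a simulated annotator that accepts or
    corrects its suggestions. Includes a synthetic-histology scene generator
    at three structure scales (nuclei, tubules, epithelium), patch extraction
    and mask encoding, a two-dimensional patch embedding with diverse
    (farthest-point) sampling, SLIC-style superpixels on intensity or learned
    features, and annotation-efficiency accounting (extrapolated manual time,
    assisted human time, integer speed-up, pixel f-scores, efficiency curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
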