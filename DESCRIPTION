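Package: lvcmap
Title: Lung Vessel Connectivity Maps as Anatomical Priors for Lobe Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fuzzy-connectedness neighbor-code maps from chest CT
    volumes, converts them into lung vessel connectivity (LVC) unit-vector
    fields via the generational strongest-neighbour walk, and summarises
    per-lobe vessel orientation with a Wilks' lambda MANOVA separability
    test. Also provides lobe segmentation evaluation metrics (Dice overlap
    and symmetric average surface distance), the standard CT preprocessing
    steps used by self-configuring segmentation pipelines (median-resolution
    resampling, percentile clipping, z-score normalisation, weighted
    multitask loss combination), and a synthetic vascular phantom generator
    with planted per-lobe orientations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
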