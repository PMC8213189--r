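Package: escortHist
Title: Escort-Histogram Comparison of Stained Histology Image Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical comparison of two ensembles (treated versus control)
    of 8-bit RGB microscopy images of stained histological sections. Pools
    per-image intensity histograms under a fixed-shift model, computes the
    maximum-likelihood estimate of the group histogram, compares groups with
    a two-sample Kolmogorov-Smirnov test, and scans one-parameter escort
    families of the estimated histograms to profile the Hellinger distance
    and Shannon-entropy difference as functions of the escort parameter beta.
    Includes a synthetic stained-histology image generator with ground truth
    (per-image logit shifts, cluster blobs) for calibration and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    jpeg,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
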