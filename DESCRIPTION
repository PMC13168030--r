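Package: standmetrics
Title: Seedling Stand Reconstruction and Sowing-Quality Indices from
    Top-View Depth Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures within-row plant spacing of emerged seedlings from
    per-frame keypoint detections and depth maps acquired by a nadir
    stereo camera on a moving field platform, and evaluates sowing
    quality with the ISO 7256/1-1984 indices (quality of feed index,
    multiple index, miss index, coefficient of variation). Implements
    RGB/depth frame alignment, robust neighbourhood-median depth
    extraction with invalid-pixel filtering, pinhole back-projection to
    metric 3D coordinates, motion-gated cross-frame plant tracking with
    ego-motion compensation, world-frame aggregation, row clustering and
    ordered spacing series. Includes a synthetic field/camera simulator
    (planted rows with miss and multiple events, detection jitter, depth
    noise and dropout) that produces pipeline inputs together with
    ground truth, so the whole measurement chain is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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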