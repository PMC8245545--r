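Package: slitflow
Title: Video Analysis of Red Blood Cells Crossing a Microfluidic Slit Barrier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies label-free brightfield videos of red blood cells
    flowing past a microfluidic slit barrier into healthy and rare hereditary
    hemolytic anemia (RHHA) classes. Provides a synthetic slit-barrier video
    generator with per-cell ground truth, multi-page TIFF / PNG frame-stack
    IO and barrier-region cropping, circular Hough transform cell detection
    with fixed-size ROI extraction, pluggable feature coding (handcrafted
    shape descriptors or a pretrained-CNN pool5 layer), unsupervised
    low-variance feature elimination, linear one-vs-all support vector
    machine scoring under leave-one-video-out cross-validation, and the
    cooperative video-level decision rules (majority voting,
    unhealthy-percentage limit, maximum trustiness) with confusion-matrix
    and efficiency reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
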