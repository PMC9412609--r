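Package: pnseg
Title: Pentagonal Neutrosophic Thresholding for Dermoscopic Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical computer-aided analysis of dermoscopic skin-lesion
    images: edge-preserving adaptive denoising, digital artifact removal
    (hair strands, ruler marks, dark frames) with inpainting,
    contrast-limited histogram equalization, and a two-phase lesion
    segmentation that combines a weighted global intensity threshold with a
    pentagonal-neutrosophic refinement threshold for ambiguous boundary
    pixels. Includes the full evaluation-metric suite (image quality,
    localization, segmentation and classification metrics), first-order
    image statistics, a rotation-based data-augmentation scheme, and a
    seeded synthetic dermoscopy generator with paired ground-truth masks so
    every stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
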