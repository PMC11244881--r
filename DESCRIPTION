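Package: invquant
Title: Pixel-Based Quantification of Multicellular Spheroid Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segmentation-free, pixel-based quantification of cell invasion
    from multicellular spheroids into 3D matrices. Given binarized nuclear
    images of the same spheroid at an initial and a final timepoint, the
    package segments the initial spheroid boundary, registers it onto the
    final image by centroid translation, measures per-pixel radial invasion
    distances and angles from the boundary, and computes the area change,
    mean invasion distance and the radial area moment of inertia as an
    integrative invasiveness metric. Principal component analysis of the
    invaded pixel cloud yields directional moments, principal invasion
    angles and fold-change anisotropy metrics. A synthetic image generator
    with closed-form expected metrics supports validation, and batch tools
    consolidate per-spheroid results with robust (scaled-MAD) outlier
    flagging.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
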