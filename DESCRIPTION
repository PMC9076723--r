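Package: handcover
Title: Quantifying Hand-Hygiene Skin Coverage from Paired White-Light and
    UV Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for measuring how completely alcohol-based handrub
    covers the skin in fluorescent (UV) hand-hygiene assessments. Hands
    are segmented from white-light photographs by chroma thresholding,
    fluorescent coverage is extracted from the paired UV photograph by
    hue-band and brightness filtering, and coverage is warped onto
    standard hand templates through a piecewise homography over an
    18-segment hand decomposition. Per-task observations are aggregated
    into per-pixel coverage-probability maps, and the coverage loss
    incurred by excluding individual steps of the six-step hand-hygiene
    technique is estimated by max-combination and subtraction of step
    maps. A fully ground-truthed synthetic image generator makes the
    whole pipeline testable end to end without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
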