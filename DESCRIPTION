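Package: skinpercept
Title: Psychophysical Scaling of Facial Skin-Colour Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how facial skin colour drives categorical
    impressions such as femininity-masculinity and likeability. The package
    generates face stimuli that differ only in skin colour over a whiteness
    by hue-angle grid (threshold skin segmentation, texture-preserving
    recolouring in CIELAB), scales bipolar forced-choice ratings into
    Thurstonian z-score values by the method of categorical judgement,
    quantifies intra- and inter-observer variation, and tests colour effects
    with Welch's ANOVA and Games-Howell post hoc comparisons. A synthetic
    face and synthetic observer module provides ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
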