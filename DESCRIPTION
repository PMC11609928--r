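Package: acumap
Title: Landmark-Based Acupoint Localization and Evaluation
Version: 0.1.0
Authors@R:
    person("acumap", "developers", email = "acumap@example.org", role = c("aut", "cre"))
Description: Maps anatomical landmark sets for hands (21 slots) and faces (468
    slots) to the positions of 38 named acupuncture points using declarative
    proportional-geometry rules, gated by a palm-normal hand-posture classifier
    (front/back/inside/outside) and a face-pose classifier (center/left/right).
    Ships the rule table as versioned data, pixel-to-physical calibration from a
    reference object, and a full keypoint evaluation stack: Euclidean distance
    errors with confidence intervals, object keypoint similarity (OKS),
    precision/recall and mean average precision under COCO-style greedy
    matching, and per-axis two-sample Kolmogorov-Smirnov comparisons. Seeded
    synthetic landmark generators and a small command-line interface make the
    whole pipeline testable without any external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
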