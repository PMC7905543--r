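Package: fragdisp
Title: Standardized 3D Fracture Fragment Displacement and Inter-Rater Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the displacement of a bone fragment between two rigid
    poses by two independent parameters: the transformation shift (TFS, mm),
    the displacement of the fragment center defined as the center of its
    minimal-volume oriented bounding box, and the transformation angle (TFA,
    degrees), the rotation angle of the relative rigid motion recovered by
    Horn's closed-form quaternion registration. Includes readers and writers
    for triangle meshes (STL, PLY), rigid poses (JSON), and planning tables
    (CSV); an inter-rater study pipeline (per-case and per-rater aggregation,
    one-way ANOVA with Bonferroni-corrected post hoc tests, experience
    regressions); and a synthetic fracture and rater simulator for end-to-end
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
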