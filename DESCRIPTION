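Package: vertemetry
Title: Transverse-Plane Vertebral Morphometry from Axial CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the in-plane geometry of vertebrae on axial CT
    slices of the torso: the distance from the vertebral-body centre to
    the spinous-process tip and onward to the skin, the partition of the
    body-contour area into quadrants about the vertebral centre, and the
    equal-area mapping of the resulting area aspects into a generalized
    ellipse so vertebral positions can be compared across patients
    independently of body shape. Includes a synthetic axial CT phantom
    generator with analytic ground truth, marching-squares body-contour
    extraction, scoliosis severity and curve-region classification, and
    per-level and regional cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, tools, jsonlite, yaml, RNifti
Suggests: testthat (>= 3.0.0), mgcv, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
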