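Package: antwalks
Title: Trajectory, Circular-Statistics and Panorama Analysis of Desert Ant Learning Walks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to analyse the early outdoor walks of desert ants: ingestion
    and calibration of frame-by-frame head/thorax tracking tables; per-walk path
    metrics (convex-hull area, maximum displacement, duration, stop-excluded
    speed, orientation angular velocity, straightness, sinuosity, maximum
    expected displacement); detection of on-the-spot scanning bouts; a circular
    statistics battery for displacement-test headings (Rayleigh, V, mean-direction
    confidence intervals, Watson-Williams, von Mises likelihood-ratio tests);
    rotational image difference functions between equirectangular panoramas; and
    repeated-measures group comparisons (Helmert contrasts, Welch ANOVA and t
    tests, Tukey-adjusted pairwise tests, bootstrap mean differences). Includes
    synthetic-data generators that emulate learning walks, excavation trips,
    displacement headings and parametric panoramic scenes with known ground
    truth, so the full pipeline runs end to end without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
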