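Package: pypquant
Title: Quantitative Tc-99m Pyrophosphate SPECT/CT Analysis for Cardiac
    Amyloidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of myocardial technetium-99m pyrophosphate
    uptake from reconstructed SPECT/CT volumes for the assessment of
    transthyretin amyloid cardiomyopathy. Provides phantom-based
    cross-calibration to body-weight standardized uptake values (SUV),
    heart and aortic volume-of-interest differentiation metrics
    (heart-to-aorta SUV ratio, planar heart-to-contralateral-lung ratio),
    left-ventricular polar maps with AHA 17-segment parcellation, regional
    heterogeneity and burden indices (segmental coefficient of variation,
    septal-lateral difference score, base-to-apex variability, total
    cardiac SUV), and the accompanying nonparametric cohort statistics
    (Kruskal-Wallis with Steel-Dwass all-pairs comparisons, Fisher exact
    tests, Pearson correlation). Includes seeded digital cardiac and
    cylinder phantom generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
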