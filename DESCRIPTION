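Package: countershade
Title: Countershading Camouflage Under Directional Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models countershading camouflage for a three-dimensional body
    under a directional light field. Computes the irradiance pattern on a
    triangle-mesh body under a CIE general sky with a direct sun beam and a
    diffuse ground term, derives the optimal countershading reflectance
    that cancels apparent shading in a reference orientation, and
    quantifies how the apparent shading (max minus min outgoing radiance)
    grows as the body pitches, rolls or yaws away from that orientation.
    Also generates visual-search stimuli (one ellipsoidal target among
    folded-leaf distractors), balanced trial designs, synthetic observer
    responses with participant-level random effects, and the matching
    statistical analysis: binomial and Gamma generalized linear mixed
    models with likelihood-ratio tests, Tukey single-step pairwise
    comparisons, and set-size search-efficiency summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Matrix,
    multcomp,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
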