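Package: breastkin
Title: Breast Skin Deformation Modelling from Arm-Abduction Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and predicting breast skin deformation of
    older women during arm abduction from motion-capture marker data.
    Provides a seeded synthetic-trial generator, marker kinematics (arm
    abduction angle and twelve inter-marker breast line lengths), gray
    relational analysis for screening candidate predictors, a single
    hidden-layer feedforward network with five backpropagation training
    algorithms (gradient descent, momentum, variable learning rate,
    resilient propagation, Fletcher-Reeves conjugate gradient), particle
    swarm optimization of network weights and a PSO-seeded hybrid trainer,
    regression metrics (MSE, Pearson R, MAPE), and an end-to-end pipeline
    with reproducibility manifests. Published anthropometry and reference
    weight tables are shipped as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
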