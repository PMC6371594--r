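Package: sharedreach
Title: Vision-Aided Shared Control Simulation for Brain-Machine Interface
    Reaching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale simulator and library for a vision-aided
    brain-machine interface (BMI) training rig: detection of green target
    objects in RGB-D images by colour-ratio segmentation, 3x3 erosion and
    divisive hierarchical clustering; camera calibration from pixel
    coordinates and depth indices to metric positions in the robot frame;
    forward and inverse kinematics of a 3-DOF anthropomorphic arm from its
    Denavit-Hartenberg parameters; an artificial-potential shared controller
    that infers the intended target from a stream of decoded hand-velocity
    vectors and blends the ideal approach direction with the decoded command
    (blending parameters alpha and beta); synthetic scene and decoded
    trajectory generators; and evaluation metrics including shortest-distance
    improvement, blending-parameter sweeps, and chance level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
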