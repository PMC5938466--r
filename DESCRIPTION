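Package: artirot
Title: Standardized Rigid Rotations of Articulated Three-Dimensional
    Landmark Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes articulation-induced translation and rotation from
    three-dimensional landmark data gathered on multi-part (articulated)
    anatomical structures, such as a humerus and radioulna or a skull and
    mandible.  Each structure is rigidly translated and rotated -- using
    axis-angle (Rodrigues) rotation matrices, never scaling or reflection
    -- into a standardized pose in which the two structures meet at a
    user-chosen angle, so that multi-structure configurations become
    comparable across specimens and can be passed to downstream geometric
    morphometric analyses.  Includes native readers and writers for the
    TPS landmark interchange format, specimen matching and array joining
    utilities, a synthetic fixture generator for articulated specimens
    with known ground truth, a per-specimen 3D plot, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    optparse,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
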