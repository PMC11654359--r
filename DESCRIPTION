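Package: ethotrack
Title: Zone Occupancy, Kinematics and Unsupervised Ethogramming for
    Animal Pose Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@ethotrack.org",
           role = c("aut", "cre"))
Description: Post-processing of animal pose-estimation tracks from a
    four-quadrant linear-track place-preference assay. Reads and writes
    pose tracks in the SLEAP analysis HDF5 layout, repairs short
    detection gaps, scores per-second quadrant occupancy from a head
    anchor, converts pixel trajectories to physical distance and
    per-node velocity, clusters frames into behaviors with k-means and
    embeds them with PCA or UMAP, and compares groups through an
    assumption-gated parametric/nonparametric decision tree with
    Benjamini-Hochberg correction. A Markov-chain locomotion simulator
    produces sessions with ground-truth occupancy and behavior labels so
    that every stage of the pipeline can be validated without video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    rhdf5,
    uwot,
    car,
    multcomp,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'skeleton.R'
    'accessors.R'
    'pose-io.R'
    'trackmetrics.R'
    'ethogram.R'
    'stats.R'
    'synthetic.R'
    'app.R'
    'show-methods.R'
    'utils.R'
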