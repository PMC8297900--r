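Package: attachkin
Title: Movement-Based Attachment Classification from Pose-Keypoint Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic secure/insecure attachment rating from doll-play
    sessions recorded on video: reads OpenPose-style keypoint sequences,
    extracts hand-kinematic features (position, inter-hand distance, speed,
    acceleration, 1-D trajectory, presence), segments them into fixed-length
    non-overlapping windows, classifies each window with a recurrent sequence
    model or a window-summary logistic baseline, aggregates windows into a
    per-child rating by majority vote, and evaluates the pipeline under the
    Leave-One-Child-Out protocol. Also provides inter-measure agreement
    statistics on categorical attachment codings (percent agreement,
    discordance counts, Cohen's kappa, two-way collapses of the four-way
    ABCD coding) and a seeded class-conditional motion simulator so the full
    pipeline is testable without real child videos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
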