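Package: wormembryo
Title: Quantifying C. elegans Embryonic Behavior from Tracked Seam-Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the behavior of late-stage Caenorhabditis
    elegans embryos. Implements multiple-hypothesis hypergraph tracking (MHHT)
    of the 20 seam-cell nuclei through noisy 3D detection sets, including
    covariance-weighted posture and movement cost models, Murty K-best
    assignment with gating, graphical interpolation of missed detections, and
    self-intersection pruning. Downstream analyses cover dorsoventral
    bend-angle profiles and their principal-component decomposition
    ("eigen-embryos"), flip detection and motif classification, trajectory
    statistics (mean squared displacement, diffusion coefficients, weighted
    embryo speed, behavioral bouts), the slow-wave-twitch (SWT) spectral
    power-ratio statistic for brightfield motility recordings, and calcium
    transient and quiescence detection for ratiometric GCaMP/mCherry imaging.
    A bundled simulator generates ground-truth embryo trajectories, corrupted
    detections, twitch tallies, brightfield movies, and calcium traces so that
    every analysis is testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    zoo
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
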