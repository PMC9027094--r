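Package: pherotrack
Title: Pheromone-Guided Polarity-Site Movement in Mating Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and quantitative analysis of polarity-site search
    dynamics in mating budding yeast. Simulates persistent random walks of
    cortical polarity sites on touching spherical cells, optionally biased
    along the steady-state point-source pheromone gradient c(r) = S/(4*pi*D*r);
    renders the walks into synthetic confocal z-stack time series with
    fiducial beads, stage drift and shot noise; tracks sites by thresholded
    3D intensity-weighted centroids with bead-based drift correction;
    quantifies chemotropic guidance with a tangent-plane direction statistic
    (the angle between each movement step and the optimal direction toward
    the partner's polarity site); detects polarity-site encounters and
    classifies commitment versus kiss-and-run outcomes; and compares
    distributions with two-sample Kolmogorov-Smirnov tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    rlang,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
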