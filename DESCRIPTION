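Package: allosTE
Title: Allosteric Communication Analysis with Elastic Network Transfer
    Entropy and ANM-Driven Transition Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of allosteric communication in proteins from
    C-alpha coordinates. Builds Gaussian network models (GNM), computes
    Gaussian transfer entropy between residue fluctuations at a chosen
    time delay together with collectivity-weighted source scores (TECol),
    detects allosteric peaks and tests their co-localization with
    reference residue sets by randomization, simulates conformational
    transitions between two conformers by iterative anisotropic network
    model mode deformation with coarse-grained relaxation (ANM-LD), and
    derives equal-time and time-delayed dynamic cross-correlation maps
    with leader/follower directionality calls. Includes generators for
    synthetic elastic structures, conformer pairs and overdamped Langevin
    fluctuation trajectories with known ground truth, so the whole
    pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    MASS
Config/testthat/edition: 3
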