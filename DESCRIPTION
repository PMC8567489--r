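Package: cortbs
Title: Cortical Backscatter Simulation, Pore-Size Inversion, and Fracture
    Discrimination Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates cortical-bone pore microstructures together with their
    pulse-echo ultrasound and HR-pQCT-like imaging signatures, and implements
    the cortical backscatter (CortBS) processing chain: compound beamforming,
    periosteal surface detection with inclination gating, normalized
    depth-dependent backscatter spectra, frequency-dependent attenuation and
    backscatter coefficients, and regularized inversion of the cortical
    pore-diameter distribution from the backscatter coefficient using a
    fluid-cylinder modal scattering kernel. Includes site-matched micro-CT
    cortical morphometry (Burghardt-style porosity, local porosity maps,
    pore-diameter and density distributions), short-term precision (RMS-CV)
    statistics, and PLS-LOOCV fracture-discrimination analysis with Monte
    Carlo subwindow variable selection, ROC/AUC and odds-ratio metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
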