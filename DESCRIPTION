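Package: vmatqa
Title: Patient-Specific VMAT QA with Detector Coalescence, Gamma Analysis
    and Statistical Process Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for patient-specific quality
    assurance of volumetric modulated arc therapy (VMAT). Generates
    MLC-structured planar dose maps, models 2D ion-chamber arrays (PTW
    729/1500 geometries) including coalescence of a couch-shifted second
    acquisition, reconstructs 3D dose on an electron-density voxel phantom
    via tissue-phantom-ratio and inverse-square scaling, evaluates
    gamma-index agreement (TG-218 style criteria), and assesses QA
    performance with individuals/moving-range control charts, process
    capability indices, and ROC-based error-detection sensitivity under
    injected delivery errors (DLG widening, MU output scaling).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
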