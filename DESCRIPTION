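Package: sptfa
Title: Single-Protein Tracking and Super-Resolution Analysis of Focal
    Adhesion Proteins
Version: 0.1.0
Authors@R:
    person("sptfa", "maintainers", email = "sptfa@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-particle tracking (sptPALM) and
    3D single-molecule localization data of membrane and focal-adhesion
    proteins. Implements mean-squared-displacement (MSD) based motion
    classification of trajectories into immobile, confined and freely
    diffusing populations inside and outside focal adhesions, confined
    diffusion model fitting, kymograph-based immobilization dwell-time
    and rearward-speed measurement from super-resolved time-lapses,
    TIRF/epifluorescence membrane-fraction and focal-adhesion enrichment
    photometry, axial (z) localization profiling with lateral drift
    correction, and a synthetic-data generator providing ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
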