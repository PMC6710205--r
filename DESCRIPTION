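Package: dvrkit
Title: Model-Based Dynamic Vasomotor Reactivity Physiomarkers from
    Cerebral Hemodynamic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the Dynamic Vasomotor Reactivity (DVR) physiomarker
    from resting-state cerebral hemodynamic recordings: beat-to-beat
    reduction of arterial blood pressure (ABP), cerebral blood flow
    velocity (CBFV) and end-tidal CO2 (ETCO2) waveforms; two-input linear
    dynamic modelling of CBFV from ABP and ETCO2 via Laguerre-basis kernel
    expansion fit by least squares; and the DVR index itself, the
    model-predicted CBFV response to a 5-second ETCO2 pulse averaged over
    5 seconds with ABP held at baseline. Includes the cohort-level
    statistical layer (Welch group tests, chi-square tests, fixed-effects
    covariate adjustment, pairwise Pearson correlations, simple
    regression), voxelwise correlation of DVR with diffusion-tensor
    imaging metric volumes with per-region significant-voxel tables, and
    seeded synthetic-data generators (hemodynamic systems, raw waveforms,
    cohort tables, voxel datasets) so the whole analysis is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
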