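Package: fnirsinc
Title: Quantifying the Impact of Hair and Skin Characteristics on fNIRS
    Signal Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how participant-level factors (hair colour,
    type, texture and thickness, skin pigmentation, head size, age and sex)
    affect the signal quality of continuous-wave functional near-infrared
    spectroscopy (fNIRS) recordings. Implements channel-level quality metrics
    (uncorrected and source-power-corrected signal means, the scalp coupling
    index), a combined hair-skin metric with inclusivity groups, the
    associated statistical battery (Mann-Whitney tests with Benjamini-
    Hochberg correction, Spearman correlation with robust linear fits and
    percentile fold changes, multicollinearity-screened robust multiple
    regression with variance inflation factors and Cohen's f-squared), a
    noise-equivalent-power analysis of channel pruning across detector
    sensitivities, and a task GLM with a modified-gamma haemodynamic
    response and short-separation regression. A synthetic-data module
    generates cohorts, probes, stimulus designs and raw intensity
    recordings with the statistical structure these analyses assume, so the
    whole pipeline runs end-to-end without any acquisition hardware.
    Recordings are read and written as SNIRF (HDF5).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
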