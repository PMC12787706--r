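Package: mwirvitals
Title: Multi-Vital Sign Extraction from Mid-Wave Infrared Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for noncontact vital-sign monitoring with a single
    mid-wave infrared (MWIR) thermal camera. Exhaled breath is visualized
    through the 4.3 um CO2 absorption band by temporal mean subtraction;
    respiratory and heart rates are estimated from region-of-interest
    time series with zero-phase Butterworth bandpass filtering and
    time-domain (peak-interval) or frequency-domain (FFT spectral peak)
    rate estimators; body temperature is read at the inner canthus after
    threshold segmentation; exhaled-airflow velocity and CO2 volume rate
    are estimated by spatiotemporal image velocimetry (STIV) using
    gradient-tensor orientation of space-time images; method agreement is
    quantified with Bland-Altman statistics, the within-LOA agreement
    rate, Pearson correlation, RMSE and a normality-gated group
    comparison. A seeded synthetic thermal-video phantom with known
    ground truth supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
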