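Package: sensorscreen
Title: Field-Stimulation Screening and Biophysical Analysis for Fluorescent Neurotransmitter Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput screening of genetically
    encoded fluorescent neurotransmitter sensor variants by field stimulation
    of cultured neurons, together with the biophysical and circuit-level
    statistics used to characterize the winning variants. Includes a
    ground-truth synthetic data generator (well movies, titrations,
    stopped-flow traces, direction-tuned trial matrices), per-pixel
    Mann-Whitney responsive-pixel detection with photobleach correction,
    dF/F0 peak and kinetics metrics, plate-level quality control with
    in-plate control normalization and joint sensitivity/expression variant
    selection, Hill and pH sigmoid and stopped-flow monoexponential curve
    fitting, and direction-selectivity statistics (response amplitude index,
    trial-to-trial reliability, motion SNR, circular variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
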