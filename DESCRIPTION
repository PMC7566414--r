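Package: bhscale
Title: Breath-Hold Calibration of Task fMRI Activation
Version: 0.1.0
Authors@R: person("bhscale", "maintainers", email = "maintainers@bhscale.org",
    role = c("aut", "cre"))
Description: Voxel-wise calibration of task-evoked BOLD fMRI activation by the
    breath-hold (hypercapnic) hemodynamic response. Fits a gamma-variate
    response model to breath-hold runs, maps activation by cross-correlation
    against block reference waveforms and by GLM with canonical-HRF regressors,
    applies Monte-Carlo cluster-extent thresholds, and scales task beta maps by
    the breath-hold response amplitude to suppress vascular (non-neural)
    variability. Includes a synthetic 4D BOLD phantom with known tissue
    structure, vascular gains, and neural amplitudes for end-to-end validation,
    plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
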