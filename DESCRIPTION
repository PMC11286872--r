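Package: cortivis
Title: Virtual-Patient Simulation of Human Visual Cortical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the perceptual consequences of electrical stimulation of
    human primary visual cortex (V1) through implanted surface or depth
    electrodes. Converts biphasic pulse trains into perceived-brightness time
    courses via a cascade of fast leaky current integration, refractory
    attenuation of spiking strength, slow gamma-kernel integration, and a
    compressive output nonlinearity. A conformal log-polar retinotopic map
    links visual-field coordinates to the flattened cortical surface, on which
    orientation-pinwheel, ocular-dominance and on/off-subunit maps are
    synthesized from bandpass-filtered complex white noise. Phosphenes are
    rendered as current-weighted sums of two-subunit receptive fields and
    quantified by image moments or Gaussian fits. Includes electrode-array
    design tools based on optimal cortical sampling, detection-threshold
    search, sensitivity normalization, and drivers for strength-duration and
    phosphene-size experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
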