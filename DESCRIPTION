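Package: cestsynth
Title: Partially Synthetic CEST Data and Machine-Learning Quantification of the
    Amide Proton Transfer Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A platform for quantitative chemical exchange saturation transfer
    (CEST) MRI at 9.4 T. Provides closed-form rotating-frame signal models
    (Lorentzian lines, exchange-dependent relaxation R_ex, effective water
    relaxation R_eff, and an inverse-summation Z-spectrum composer), a
    multi-pool Bloch-McConnell simulator for tissue-mimicking Z-spectra with
    ground-truth amide proton transfer (APT) spectra, six-pool Lorentzian
    decomposition of Z-spectra, builders for partially and fully synthetic
    training corpora, and a small feed-forward neural network that predicts
    the amplitude and width of the amide CESTR peak from sparsely sampled
    Z-spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
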