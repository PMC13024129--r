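Package: radarbp
Title: Contactless Blood-Pressure Estimation from FMCW Radar Pulse Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for contactless blood-pressure estimation
    from frequency-modulated continuous-wave (FMCW) radar. Provides a
    parametric chest-motion and hemodynamics simulator, the radar signal
    processing front end (static-clutter suppression, DC-offset removal,
    digital beamforming with range-angle selection, extended
    differentiate-and-cross-multiply phase demodulation, and pulse-wave
    extraction), an unsupervised variational-autoencoder signal-quality
    index for radar pulse-wave screening, label-preserving augmentation
    operators, a Mamba-enhanced multi-task U-Net that jointly regresses
    systolic and diastolic blood pressure and reconstructs the arterial
    waveform, and a training and evaluation harness with AAMI and BHS
    grading. Neural components run on a lightweight reverse-mode automatic
    differentiation engine included in the package, so no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    pracma,
    pROC,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
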