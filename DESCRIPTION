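Package: aefmeg
Title: Single-Trial Auditory Evoked Field Enhancement and Recognition for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting single-trial auditory evoked magnetic fields
    (AEFs) in multichannel magnetoencephalography (MEG) recordings. Implements
    a sensor-neighbourhood correlation enhancement that concentrates
    single-trial signal energy over its cortical source, the surrounding
    preprocessing chain (audio-channel event marking, signal-space projection
    for blink and cardiac artifacts, IIR notch and linear-phase FIR low-pass
    filtering, trial interception and robust power screening), normalized-energy
    topographic imaging of trials as 224 x 224 scalp maps, and a compact
    convolutional image classifier separating evoked trials from empty-room
    noise. A seeded synthetic MEG session generator (spherical-cap sensor
    lattice, current-dipole forward fields, triphasic P50/N100/P200 waveforms,
    structured noise and artifacts) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
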