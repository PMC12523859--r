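Package: iolbench
Title: Virtual Optical Bench for Functional Classification of Diffractive
    Intraocular Lenses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fourier-optics model eye for simulating through-focus image
    quality of diffractive multifocal intraocular lenses. Builds and
    calibrates sinusoidal diffractive phase profiles to a target
    far/intermediate/near light split, computes through-focus polychromatic
    MTF-area (MTFa) curves across pupil diameters, translates MTFa into
    predicted visual-acuity defocus curves with a registry of empirical
    prediction models, and assigns the depth-of-field functional
    classification (Full/Partial; Continuous/Smooth/Steep) per pupil
    diameter and model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
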