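Package: MsiDeconv
Title: Charge-State Deconvolution of Native Protein Mass Spectrometry
    Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-pixel charge-state deconvolution of native protein mass
    spectrometry imaging (MSI) datasets that are not isotopically resolved.
    Reads m/z-domain imzML file pairs (continuous and processed dialects),
    stores pixel spectra with positional metadata in an HDF5 container,
    deconvolves every pixel with a single shared parameter set by iterative
    Bayesian charge assignment with an optional Richardson-Lucy peak-width
    step, and exports mass-domain imzML for downstream MSI software. Ion,
    composite-ion and mass images can be extracted and charge-state
    assignments validated by cosine similarity of ion images against mass
    images. A seeded synthetic-data generator emulates multi-charge protein
    envelopes with spatial abundance patterns so the full workflow is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    xml2,
    rhdf5,
    digest,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
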