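Package: saxspipe
Title: Plug-In Pipeline for Reduction of Scanning SAXS and GISAXS Detector Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrated reduction of two-dimensional small-angle X-ray
    scattering (SAXS) and grazing-incidence SAXS (GISAXS) detector frames:
    pixel-to-q mapping for transmission and grazing geometries, radial and
    azimuthal integration, GISAXS line cuts with regions of interest,
    background/monitor/binning corrections with Poisson error propagation,
    sequential composite peak fitting (Gaussian, Lorentzian, pseudo-Voigt)
    across frame series, and bone-tissue nanostructure parameters (Porod
    T parameter, azimuthal rho parameter, predominant mineral orientation).
    Results accumulate in a typed table produced by a validated plug-in
    pipeline that runs offline on file lists or online on a growing
    directory, and export as spreadsheets and scan-grid maps. A synthetic
    frame generator with analytic ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
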