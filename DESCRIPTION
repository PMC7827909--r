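Package: smearMSI
Title: MALDI-TOF Mass Spectrometry Imaging Analysis of Blood Smears
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell-resolution MALDI-TOF mass spectrometry
    imaging (MSI) of blood smears. Provides elemental-formula and
    adduct-resolved monoisotopic m/z arithmetic, imzML input/output, a
    ground-truth synthetic smear simulator, spectral preprocessing
    (TIC normalization, fixed-width m/z binning to centroids, relative
    intensity thresholding, top-K feature selection), region-of-interest
    based differential m/z expression between blood-cell and plasma-remnant
    regions, adduct-resolved metabolite annotation at a fixed mass
    tolerance, and ion-image rendering with median smoothing and Lanczos
    interpolation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    png,
    grDevices,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: MassSpectrometry, ImagingMassSpectrometry, Metabolomics,
    Preprocessing, DifferentialExpression, SingleCell
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
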