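Package: toposcreen
Title: Micro-Topography Screening of Keratinocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing TopoChip-style micro-topography
    screens of epidermal stem cell differentiation. Generates virtual libraries
    of 300x300 micrometre topography units composed of randomised primitive
    shapes, computes surface descriptors (coverage, spectral wavenumber bands,
    line length, circle diameter, rotational irregularity), simulates screens
    with a planted differentiation/morphology response, quantifies per-cell
    transglutaminase-1 positivity and cell shape from rendered images or
    measurement tables, selects hits by robust median +/- k*SD thresholds, and
    fits cross-validated binary classification trees that relate topography
    descriptors to the screened phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
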