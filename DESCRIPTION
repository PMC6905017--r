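Package: rootmorph
Title: Machine-Vision Morphometry of Excavated Plant Root Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures root morphological parameters (projected and lateral
    surface area, average diameter, total length, volume) from photographs of
    excavated seedling roots laid on a background plate of known physical size.
    Implements the full measurement chain: blue-channel grayscale conversion,
    histogram valley and iterative (ISODATA-style) threshold segmentation,
    median filtering, binary morphological cleanup, Zhang-Suen skeletonization
    with chain-code length measurement, inscribed-circle diameter estimation,
    and a cylindrical-approximation model for surface area and volume. Includes
    a synthetic root-image generator with analytic ground truth for validation,
    and the instrument cross-calibration statistics (error analysis,
    independent-samples t-test with Levene screening, linear gain/offset fits)
    used to certify such systems against a reference instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
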