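Package: limbmorph
Title: Residual-Limb Surface Morphometry for Prosthetic Interface Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies prosthetic-interface-induced soft-tissue deformation of
    a residual limb from segmented surface models. Computes nearest-vertex
    distance fields from an internal hard-tissue surface to the skin surface
    and their vertex-count-normalised histograms; registers limb models across
    interface conditions by landmark-based rigid fitting refined with iterative
    closest point, scored with Hausdorff distances; and produces signed
    skin-to-skin comparison maps flagging where one interface is more
    compressive. Includes STL/PLY readers and writers, triangle-mesh plane
    trimming, and a parametric transtibial limb phantom generator with
    closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
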