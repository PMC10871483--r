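Package: lungmorph
Title: Micro-CT Morphometry of the Developing Lung
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of terminal air-space development from
    micro-computed tomography volumes of contrast-stained lungs. Implements
    seeded region growing of the air lumen within a gray-tolerance band,
    voxel and isosurface estimators for region-of-interest volume and
    surface area with ROI subtraction to obtain terminal air-space metrics,
    fractionator-style line-intercept stereology for air-space diameter and
    septum thickness, and allometric analysis of lung volume and surface
    area against body mass. Ships a synthetic developing-lung phantom
    generator with voxel-level ground truth for validating every stage of
    the pipeline, and a packaged per-specimen morphometry table for the gray
    short-tailed opossum from late fetal life to adulthood.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
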