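Package: ecodegrade
Title: Mapping and Assessment of Degraded Ecosystem Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A national-scale ecosystem degradation assessment pipeline:
    per-ecosystem composite degradation scoring (a six-criterion grassland
    degradation index, cave conservation index, multicriteria river, lake
    and coastal schemes), per-pixel canopy-cover trend analysis for forests,
    degraded-feature density grids, Getis-Ord Gi* hotspot detection with
    confidence binning, natural-breaks (Fisher-Jenks) classification, zonal
    summaries, and ROC/AUC validation against ground-truth points.  Includes
    a seeded synthetic-landscape generator with known ground truth for
    end-to-end testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
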