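Package: esvrisk
Title: Ecosystem Service Value and Landscape Ecological Risk on Gridded Land Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based assessment of ecosystem service value (ESV, equivalent-factor
    method) and the landscape ecological risk index (LERI) on categorical land-use
    rasters, with natural-breaks grading, bivariate Moran's I and LISA cluster typing,
    geographical-detector q statistics with interaction detection, weighted standard
    deviational ellipses, and CA-Markov land-use projection validated by Cohen's kappa.
    Includes a seeded synthetic dry-valley landscape generator (land use, elevation and
    correlated driver surfaces) so the full pipeline runs end-to-end without external
    data, and reads and writes ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
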