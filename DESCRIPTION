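Package: octseg
Title: Shortest-Path Segmentation and Thickness Agreement Analysis for Retinal OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of four retinal boundaries (inner
    limiting membrane, inner/outer photoreceptor segment junction, retinal
    pigment epithelium centerline and outer border) in spectral-domain OCT
    B-scans by node-weighted shortest-path dynamic programming, with A-scan
    flattening by neighbour cross-correlation, optional anchor points to
    guide the path, thickness quantification at the foveal center, the
    central 1-mm line and the 6-mm line, and the paired-comparison
    statistics (paired t-tests, Pearson correlation, Bland-Altman limits,
    repeatability coefficients, device-conversion regression) used to
    assess agreement between OCT instruments. Includes a synthetic B-scan
    phantom generator with known ground truth so the whole pipeline can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
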