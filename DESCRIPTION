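Package: junctmorph
Title: Morphometry of Individual Cell-Cell Junctions in Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of individual cell-cell junctions in
    single-channel fluorescence images of junctional markers (E-cadherin,
    VE-cadherin, beta-catenin and co-stained proteins). The package
    skeletonizes cell boundaries to a one-pixel-wide edge map, identifies
    tricellular corners, extracts corner-to-corner interfaces, and measures
    each junction with a repertoire of primary parameters (contour and
    straight-line lengths, dilation-band areas, marker area and intensity)
    and secondary, size-normalized parameters (linearity indices, coverage
    index, interface occupancy, intensity per interface area, cluster
    density). Scripted skeleton and corner edits replace interactive
    correction, a PSNR quality gate flags images too noisy for automatic
    skeletonization, and a synthetic Voronoi-monolayer generator provides
    exact geometric and photometric ground truth. Group comparison
    (Mann-Whitney, ANOVA with Games-Howell post-hoc) and control-normalized
    phenotype fingerprints are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    stats,
    graphics,
    grDevices,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
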