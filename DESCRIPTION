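Package: benthomap
Title: Biotope Mapping from Low-Altitude Aerial Imagery and Photoquadrat Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, tested pipeline for mapping shallow-water biotopes by
    combining low-altitude RGB aerial imagery with underwater photoquadrat
    surveys. Implements optical depth-class estimation from ln-transformed
    band indices via object-based image analysis (multiresolution
    region-merging segmentation and KNN classification), per-depth-class
    substrate classification, resemblance-based community statistics
    (Bray-Curtis, hierarchical clustering with similarity-profile testing,
    similarity percentages, analysis of similarities, non-metric
    multidimensional scaling, distance-based linear modelling and canonical
    analysis of principal coordinates), and spatial extrapolation plus
    permutation validation of biotope distribution. Includes a synthetic
    scene generator (radiative water-column model over a known bathymetry,
    substrate patches, Dirichlet-multinomial point-intercept communities)
    providing ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    vegan,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
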