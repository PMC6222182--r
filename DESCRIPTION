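Package: bronchonav
Title: Virtual Bronchoscopy Route Planning from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans bronchoscopic biopsy routes from chest CT volumes. Segments the
    airway lumen with multiscale second-derivative-of-Gaussian tubularity filtering
    plus seeded region growing, reduces the segmentation to a centerline skeleton,
    encodes it as a rooted (binary) airway tree held in a node-adjacency matrix and
    a matrix of 3D centerline segments, finds the tree path from the trachea to the
    airway point closest to a user-selected lesion, and translates that path into
    ordered quadrant-based navigation instructions ("go up-left", "go right", ...)
    by projecting the child branches through a virtual endoluminal camera at every
    bifurcation. A synthetic airway phantom generator with exact ground truth makes
    the whole pipeline testable without patient data. Reads DICOM series and NIfTI
    volumes, writes NIfTI masks, Wavefront OBJ airway meshes, and JSON/text/PNG
    roadmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
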