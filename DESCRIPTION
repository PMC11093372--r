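Package: lcnet
Title: Connectomics of the Osteocyte Lacuno-Canalicular Network from 3D
    Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to turn confocal-like 3D fluorescence image stacks of
    rhodamine-stained bone into a spatial network (connectome) of the
    osteocyte lacuno-canalicular network, and to quantify that network:
    dual-pass difference-of-Gaussians segmentation of canaliculi and
    lacunae, calcein-label based partitioning of the cortex, topology
    preserving 3D skeletonization, cubic-spline edge fitting with arc
    length measurement, canalicular density (Can.Dn) on sub-volume grids,
    canalicular length (Can.Ln) and degree-of-connectivity (DoC)
    distributions, cortical density profiles, and density-connectivity
    regressions.  A synthetic phantom generator produces ground-truth
    branching networks and renders them into image stacks so that every
    stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
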