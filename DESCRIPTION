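Package: arimap
Title: Activation Recovery Interval Mapping from Unipolar Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ventricular repolarization from contact
    electroanatomic maps. Detects per-beat activation times (maximal negative
    QRS downslope) and repolarization times (Wyatt T-wave fiducial) on
    unipolar electrograms, computes activation recovery intervals (ARIs) with
    a beat-consistency filter, interpolates site measurements onto a
    triangulated endocardial shell by global inverse-distance (Shepard)
    weighting, transfers imaging-derived tissue labels (scar, border zone,
    healthy), computes geodesic distance to the scar-healthy interface with a
    2 mm exclusion band, derives local ARI and repolarization-time gradients
    on the mesh, and runs tissue- and pacing-stratified statistical
    comparisons (paired t, repeated-measures and unbalanced ANOVA, Pearson
    correlation, percentile outlier exclusion). A synthetic-data module
    generates meshes, scar labels and electrograms with analytically known
    fiducials for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
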