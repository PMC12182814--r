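Package: lvmech
Title: Regional Left-Ventricular Mechanics, Dyssynchrony, and Contraction-Pattern Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying regional left-ventricular mechanics from
    short-axis myocardial velocity fields. Tracks myocardial material points
    through a cardiac cycle, derives radial and circumferential strain over
    the 16-segment American Heart Association model, and computes per-slice
    mechanical dyssynchrony statistics (standard deviation and maximum of
    time-to-peak strain, strain-rate cross-correlation lag, and the
    Fourier-based radial uniformity ratio estimate). Includes an
    incompressible annular contracting-ventricle phantom with closed-form
    strain truth, a synthetic patient-cohort simulator with planted
    contraction phenotypes and cluster-dependent time-to-event outcomes,
    Ward hierarchical clustering with majority-vote selection of the number
    of clusters across a suite of cluster-validity indices, and
    Kaplan-Meier/Cox survival analysis of the discovered phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    survival,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
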