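Package: diffusemap
Title: Reconstruction and Disorder-Model Analysis of Diffuse X-Ray
    Scattering from Protein Crystals
Version: 0.1.0
Authors@R:
    person("diffusemap", "developers", email = "diffusemap@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct three-dimensional diffuse scattering maps
    from rotation-method X-ray diffraction images and to interpret them with
    crystal-disorder models.  Detector pixels are mapped to reciprocal space
    with polarization and solid-angle corrections, Bragg-contaminated pixels
    are masked with spot prediction plus robust radial statistics, radially
    symmetric backgrounds are removed by reference-profile fitting and
    principal-component analysis, and corrected intensities are merged onto
    an oversampled reciprocal-space grid and symmetrized.  Anisotropic
    diffuse intensity is predicted under rigid-body translation and rotation,
    liquid-like motions (asymmetric-unit-confined and intermolecular),
    discrete conformational ensembles, and elastic-network covariance models,
    and fitted to experimental maps by multiplicity-weighted correlation.
    Speckle fall-off profiles and map autocorrelation diagnostics distinguish
    disorder confined to the asymmetric unit from correlations that cross
    unit-cell boundaries.  A synthetic-data module generates toy crystals,
    explicit disorder ensembles, and rendered rotation images so the whole
    pipeline can be validated against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
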