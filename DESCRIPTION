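Package: fuzzycyl
Title: Cylinder Fitting to Fuzzy Point Clouds from Terrestrial Laser Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits cylinders to 3D point clouds whose per-point measurement
    uncertainty is modelled explicitly as a trivariate Gaussian (a "fuzzy
    point cloud"). Covariances follow a terrestrial laser scanning noise
    model combining beam divergence and incidence angle; the fit minimizes
    the mean expected squared Mahalanobis distance to a tangent-line
    envelope of the cross-section circle, with an outer loop that updates
    the covariances from the current geometry estimate. Euclidean
    least-squares (Gauss-Newton) and RANSAC baselines, a deterministic scan
    simulator, and a Monte-Carlo evaluation harness with paired t-tests are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
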