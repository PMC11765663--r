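# fuzzycyl

Cylinder fitting for terrestrial laser scanning (TLS) point clouds with
explicit, per-point, anisotropic measurement uncertainty.

## What it does

TLS point clouds of cylinders — tree stems, branches, pipes — carry noise
that varies strongly across the object: the laser footprint grows with
range, and rays grazing the silhouette smear their range return along the
beam. Ordinary least squares ignores this and systematically
overestimates the radius.

`fuzzycyl` models each measured point as a trivariate Gaussian
N(μ̂ᵢ, Σᵢ) (a *fuzzy point cloud*), with Σᵢ built from a physical beam
model,

    σ_radial = d₀/4 + (R/2)·tan λ          (footprint growth)
    σ_prop   = σ₀ + σ_radial·tan α         (incidence-angle smearing)

and fits the cylinder by minimizing the mean expected squared
**Mahalanobis** distance between the Gaussians and the cross-section
circle. The circle is approximated by its envelope of t tangent lines,
for which the expectation has the closed form E[M²(L)] = τ² + 1; the
per-line values are combined in a weighted mean with weights M(ĉ)⁻³ so
distant tangent lines are negligible. Because tangent lines are flat,
the curvature-induced radius bias of direct point-to-circle distances is
avoided. The per-point covariances depend on the (unknown) geometry
through the incidence angle, so an outer loop alternates covariance
construction and fitting until the geometry converges.

Four methods are provided for comparison: `els` (Gauss–Newton Euclidean
least squares), `rels` (RANSAC + ELS), `em` (the expected-Mahalanobis
envelope fit, ELS-initialized) and `rem` (RANSAC-initialized).

## A worked example

Simulate a scan of a 5 cm cylinder from 100 m, add beam-model noise, and
fit it both ways:

```r
library(fuzzycyl)

truth <- cylinder_geometry(radius = 0.05, azimuth = 0, elevation = pi / 2,
                           center = c(0, 0, 0), length = 0.25)
scanners <- list(scanner_spec(c(0, 100, 0)))   # 100 m away
scan <- simulate_tls_scan(truth, scanners[[1]])
cloud <- sample_replicate(make_fuzzy_cloud(scan, scanners, truth), seed = 1)

fit_els <- fit_cylinder(cloud, method = "els")
fit_em  <- fit_cylinder(cloud, method = "em", scanners = scanners, t = 200)
rbind(ELS = relative_errors(fit_els, truth),
      EM  = relative_errors(fit_em,  truth))
```

```
      center_x   center_y vector_x  vector_y     radius
ELS -0.2966937  5.7560662 8.347451 2.9763878 -2.7639472
EM   1.6371798 -0.5708805 6.854273 0.5586342  0.7605164
```

The rows are relative errors in percent (center and radius normalized by
the true radius, axis-vector components raw): on this sparse, noisy
21-point scan the envelope fit's radius error (0.8 %) is several times
smaller than the least-squares one (−2.8 %), and its center error along
the beam direction (`center_y`) drops from 5.8 % to 0.6 % of the radius.

The Monte-Carlo comparison over many replicate clouds, including RANSAC
variants and paired t-tests:

```r
rep <- run_cylinder_experiment("100m", n_replicates = 50, seed = 1,
                               methods = c("els", "em"), t = 200)
print(rep)
```

A thin command-line wrapper with `simulate`, `fit` and `evaluate`
commands lives at `inst/cli/fuzzycyl.R`; scanner setups are YAML files
(see `?read_run_config`), point clouds XYZ text or ASCII PLY.

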