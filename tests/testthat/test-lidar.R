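test_that("radial beam uncertainty follows the divergence model", {
  cyl <- ref_truth()
  sc <- scanner_spec(c(0, 50, 0), exit_diameter = 4e-3,
                     divergence_half_angle = 0)
  expect_equal(sigma_radial(c(0, 0.05, 0), sc), 1e-3, tolerance = 1e-12)

  sc2 <- scanner_spec(c(0, 50, 0), exit_diameter = 0,
                      divergence_half_angle = atan(1e-4))
  expect_equal(sigma_radial(c(0, 0, 0), sc2), 2.5e-3, tolerance = 1e-9)

  sc3 <- scanner_spec(c(0, 100, 0), exit_diameter = 2e-3,
                      divergence_half_angle = atan(1e-5))
  expect_equal(sigma_radial(c(0, 0, 0), sc3), 1e-3, tolerance = 1e-9)

  # strictly increasing in range when the beam diverges
  sc4 <- scanner_spec(c(0, 0, 0), divergence_half_angle = 1e-4)
  expect_gt(sigma_radial(c(0, 60, 0), sc4), sigma_radial(c(0, 30, 0), sc4))
  expect_error(sigma_radial(c(0, 0, 0), sc4), "degenerate")
})

test_that("incidence angle covers head-on, grazing and oblique geometry", {
  cyl <- ref_truth()
  sc <- scanner_spec(c(0, 50, 0))
  expect_equal(incidence_angle(c(0, 0.05, 0), sc, cyl), 0, tolerance = 1e-9)

  # silhouette: surface normal orthogonal to the beam
  mu_sil <- c(0.05, 0, 0)
  sc_x <- scanner_spec(c(0.05, 50, 0))
  expect_equal(incidence_angle(mu_sil, sc_x, cyl), pi / 2, tolerance = 1e-9)

  mu <- c(0.05 / sqrt(2), 0.05 / sqrt(2), 0)
  a <- incidence_angle(mu, sc, cyl)
  # independent dot-product evaluation
  nrm <- mu - c(0, 0, mu[3])
  beam <- mu - sc$position
  a_ref <- acos(abs(sum(nrm * beam)) / (sqrt(sum(beam^2)) * sqrt(sum(nrm^2))))
  expect_equal(a, a_ref, tolerance = 1e-12)
  expect_equal(a, pi / 4, tolerance = 2e-3)  # far-range limit only

  expect_error(incidence_angle(c(0, 0, 0.1), sc, cyl), "degenerate")
})

test_that("incidence angle is invariant under rigid motion of the whole scene", {
  set.seed(61)
  cyl <- ref_truth()
  sc <- scanner_spec(c(0, 50, 0))
  mu <- c(0.02, 0.046, 0.03)
  a0 <- incidence_angle(mu, sc, cyl)
  for (i in 1:5) {
    R <- random_rotation3()
    shift <- stats::rnorm(3)
    ang <- axis_angles(as.numeric(R %*% cyl$axis))
    cyl_r <- cylinder_geometry(cyl$radius, ang[1], ang[2],
                               as.numeric(R %*% cyl$center) + shift, cyl$length)
    sc_r <- scanner_spec(as.numeric(R %*% sc$position) + shift)
    expect_equal(incidence_angle(as.numeric(R %*% mu) + shift, sc_r, cyl_r),
                 a0, tolerance = 1e-9)
  }
})

test_that("propagation uncertainty adds the smeared radial term with a clamp", {
  cyl <- ref_truth()
  sc <- scanner_spec(c(0, 50, 0), base_range_sigma = 1e-3)
  # head-on: alpha = 0 so sigma_prop = sigma0
  expect_equal(sigma_prop(c(0, 0.05, 0), sc, cyl), 1e-3, tolerance = 1e-9)

  # alpha = pi/4 gives sigma0 + sigma_radial
  mu45 <- c(0.05 * sin(pi / 4), 0.05 * cos(pi / 4), 0)
  sc_far <- scanner_spec(c(0.05 * sin(pi / 4), 1e6, 0))
  sr <- sigma_radial(mu45, sc_far)
  expect_equal(sigma_prop(mu45, sc_far, cyl), sc_far$base_range_sigma + sr,
               tolerance = 1e-6)

  # grazing ray: finite under the clamp
  sc_x <- scanner_spec(c(0.05, 50, 0))
  sp <- sigma_prop(c(0.05, 0, 0), sc_x, cyl)
  expect_true(is.finite(sp))
  expect_equal(sp, sc_x$base_range_sigma +
                 sigma_radial(c(0.05, 0, 0), sc_x) * tan(89.5 * pi / 180),
               tolerance = 1e-9)
  # sigma_prop >= sigma0 always
  expect_gte(sp, sc_x$base_range_sigma)
})

test_that("point covariance has the beam-frame eigenstructure", {
  cyl <- ref_truth()
  sc <- scanner_spec(c(0, 50, 0))
  mu <- c(0, 0.05, 0)  # beam along -y, head-on
  S <- build_covariance(mu, sc, cyl)
  sr <- sigma_radial(mu, sc)
  sp <- sigma_prop(mu, sc, cyl)
  expect_equal(S, diag(c(sr^2, sp^2, sr^2)), tolerance = 1e-15)

  mu2 <- c(0.03, 0.04, 0.06)
  S2 <- build_covariance(mu2, sc, cyl)
  sr2 <- sigma_radial(mu2, sc)
  sp2 <- sigma_prop(mu2, sc, cyl)
  expect_equal(det(S2), sp2^2 * sr2^4, tolerance = 1e-9)
  ev <- sort(eigen(S2, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, sort(c(sp2^2, sr2^2, sr2^2)), tolerance = 1e-12)

  # rotating the whole scene rotates the covariance consistently
  set.seed(71)
  R <- random_rotation3()
  ang <- axis_angles(as.numeric(R %*% cyl$axis))
  cyl_r <- cylinder_geometry(cyl$radius, ang[1], ang[2],
                             as.numeric(R %*% cyl$center), cyl$length)
  sc_r <- scanner_spec(as.numeric(R %*% sc$position))
  S2r <- build_covariance(as.numeric(R %*% mu2), sc_r, cyl_r)
  expect_equal(S2r, R %*% S2 %*% t(R), tolerance = 1e-12)
})

test_that("simulated scans hit the visible surface deterministically", {
  cyl <- ref_truth()
  sc <- ref_scanner(50)
  scan <- simulate_tls_scan(cyl, sc)
  expect_gte(nrow(scan), 30)
  X <- as.matrix(scan[, c("x", "y", "z")])
  radial <- sqrt(X[, 1]^2 + X[, 2]^2)
  expect_true(all(abs(radial - cyl$radius) < 1e-9))
  expect_true(all(abs(X[, 3]) <= cyl$length / 2 + 1e-9))
  # scanner-facing: the hit sees the scanner, not the back half
  to_scanner <- sweep(-X, 2, sc$position, "+")
  expect_true(all(rowSums(X[, 1:2] * to_scanner[, 1:2]) > 0))
  # deterministic
  expect_identical(scan, simulate_tls_scan(cyl, sc))
})

test_that("multi-scanner scans are unions and density scales with resolution", {
  cyl <- ref_truth()
  s1 <- scanner_spec(c(0, 50, 0), id = 0L)
  s2 <- scanner_spec(c(50, 0, 0), id = 1L)
  both <- simulate_tls_scan(cyl, list(s1, s2))
  solo <- rbind(simulate_tls_scan(cyl, s1), simulate_tls_scan(cyl, s2))
  expect_equal(both[order(both$x, both$y, both$z), ],
               solo[order(solo$x, solo$y, solo$z), ],
               ignore_attr = TRUE)

  big <- cylinder_geometry(0.2, 0, pi / 2, c(0, 0, 0), 1.0)
  coarse <- scanner_spec(c(0, 50, 0), angular_step = 0.036 * pi / 180)
  fine <- scanner_spec(c(0, 50, 0), angular_step = 0.018 * pi / 180)
  n_coarse <- nrow(simulate_tls_scan(big, coarse))
  n_fine <- nrow(simulate_tls_scan(big, fine))
  expect_gt(n_fine / n_coarse, 4 * 0.8)
  expect_lt(n_fine / n_coarse, 4 * 1.2)
})
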