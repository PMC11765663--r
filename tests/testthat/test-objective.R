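test_that("Mahalanobis distance reduces to Euclidean for identity precision", {
  expect_equal(mahalanobis_distance(c(1, 2), c(4, 6), diag(2)), 5,
               tolerance = 1e-12)
  expect_equal(mahalanobis_distance(c(1, 2, 3), c(1, 2, 3), diag(3)), 0)
  expect_equal(mahalanobis_distance(c(1, 1), c(0, 0), diag(c(4, 1))),
               sqrt(5), tolerance = 1e-12)
  expect_error(mahalanobis_distance(c(0, 0), c(1, 1),
                                    matrix(c(1, 2, 2, 1), 2)),
               "invalid precision")
})

test_that("tangent-line tau matches its closed form and a whitening cross-check", {
  # unit circle, isotropic gaussian at the center
  expect_equal(tangent_tau(c(1, 0), c(0, 0), c(1, 1)), 1, tolerance = 1e-12)
  # mean lying on the line
  expect_equal(tangent_tau(c(1, 0), c(1, 0.7), c(1, 1)), 0, tolerance = 1e-12)
  # anisotropic case forced by the formula
  expect_equal(tangent_tau(c(1, 0), c(0, 0), c(2, 1)), 0.5, tolerance = 1e-12)
  expect_error(tangent_tau(c(0, 0), c(1, 1), c(1, 1)), "degenerate line")

  # cross-check: tau equals the Euclidean distance from the whitened mean
  # to the whitened tangent line
  set.seed(91)
  for (i in 1:20) {
    sd <- stats::runif(2, 0.3, 3)
    mu <- stats::rnorm(2)
    th <- stats::runif(1, 0, 2 * pi)
    cp <- stats::runif(1, 0.3, 2) * c(cos(th), sin(th))
    tau <- tangent_tau(cp, mu, sd)
    # whiten (principal frame): x -> x / sd; the line <cp, x - cp> = 0
    # becomes <cp * sd, y> = |cp|^2
    nvec <- cp * sd
    d <- abs(sum(nvec * (mu / sd)) - sum(cp^2)) / sqrt(sum(nvec^2))
    expect_equal(tau, d, tolerance = 1e-9)
  }
})

test_that("expected squared line distance is tau^2 + 1 and matches Monte-Carlo", {
  expect_equal(expected_sq_line(0), 1)
  expect_equal(expected_sq_line(1), 2)
  expect_equal(expected_sq_line(0.5), 1.25)

  # Monte-Carlo oracle: expected squared Mahalanobis distance from a
  # Gaussian to a line, computed by sampling in the original frame
  set.seed(101)
  for (i in 1:5) {
    sd <- stats::runif(2, 0.5, 2)
    mu <- stats::rnorm(2, sd = 0.8)
    th <- stats::runif(1, 0, 2 * pi)
    cp <- stats::runif(1, 0.5, 1.5) * c(cos(th), sin(th))
    tau <- tangent_tau(cp, mu, sd)
    n <- 2e5
    X <- cbind(stats::rnorm(n, mu[1], sd[1]), stats::rnorm(n, mu[2], sd[2]))
    # Mahalanobis distance of each sample to the line via whitening
    d <- (X %*% cp - sum(cp^2)) / sqrt(sum((cp * sd)^2))
    m2 <- mean(d^2)
    se <- stats::sd(as.numeric(d^2)) / sqrt(n)
    expect_lt(abs(m2 - expected_sq_line(tau)), 4 * se)
  }
})

test_that("envelope expectation is symmetric, scale-invariant and matches a per-line oracle", {
  # full symmetry: isotropic gaussian at the circle center
  for (t in c(10, 100, 1000)) {
    expect_equal(envelope_expected_sq(c(0, 0), diag(2), c(0, 0), 1, t), 2,
                 tolerance = 1e-12)
  }
  expect_error(envelope_expected_sq(c(0, 0), diag(2), c(0, 0), 1, 2),
               "envelope too small")

  # scale invariance: scaling lengths and covariance jointly changes nothing
  set.seed(111)
  S <- random_spd2()
  mu <- c(1.4, -0.3)
  v0 <- envelope_expected_sq(mu, S, c(0.2, 0.1), 0.8, 500)
  for (s in c(0.01, 100)) {
    expect_equal(envelope_expected_sq(s * mu, s^2 * S, s * c(0.2, 0.1),
                                      s * 0.8, 500),
                 v0, tolerance = 1e-10)
  }

  # term-by-term oracle built from the exported scalar operations
  oracle <- function(mean, cov, center, r, t, eps = 1e-6) {
    e <- eigen(cov, symmetric = TRUE)
    Rot <- e$vectors
    sd <- sqrt(e$values)
    mu_f <- as.numeric(t(Rot) %*% (mean - center))
    P <- solve(diag(e$values))
    num <- den <- 0
    for (k in seq_len(t)) {
      th <- 2 * pi * (k - 1) / t
      cp_world <- r * c(cos(th), sin(th))
      cp <- as.numeric(t(Rot) %*% cp_world)
      tau <- tangent_tau(cp, mu_f, sd)
      M <- max(mahalanobis_distance(cp, mu_f, P), eps)
      num <- num + expected_sq_line(tau) / M^3
      den <- den + 1 / M^3
    }
    c(normalized = num / den, unnormalized = num / t)
  }
  set.seed(121)
  for (i in 1:5) {
    S <- random_spd2()
    mu <- stats::rnorm(2, sd = 1.5)
    ctr <- stats::rnorm(2, sd = 0.3)
    r <- stats::runif(1, 0.4, 1.6)
    o <- oracle(mu, S, ctr, r, 200)
    expect_equal(envelope_expected_sq(mu, S, ctr, r, 200),
                 unname(o["normalized"]), tolerance = 1e-9)
    expect_equal(envelope_expected_sq(mu, S, ctr, r, 200,
                                      weighting = "unnormalized"),
                 unname(o["unnormalized"]), tolerance = 1e-9)
  }
  # exterior isotropic case from first principles
  o2 <- oracle(c(2, 0), diag(2), c(0, 0), 1, 1000)
  expect_equal(envelope_expected_sq(c(2, 0), diag(2), c(0, 0), 1, 1000),
               unname(o2["normalized"]), tolerance = 1e-9)
})

test_that("envelope values converge as the envelope grows", {
  set.seed(131)
  for (i in 1:10) {
    S <- random_spd2()
    mu <- stats::rnorm(2, sd = 1.2)
    r <- stats::runif(1, 0.5, 1.5)
    v <- vapply(c(100, 1000, 10000), function(t) {
      envelope_expected_sq(mu, S, c(0, 0), r, t)
    }, numeric(1))
    expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]) + 1e-12)
  }
})

test_that("total objective normalizes to 1 at the reference geometry", {
  cyl <- ref_truth()
  sc <- ref_scanner(50)
  scan <- simulate_tls_scan(cyl, sc)
  fc <- make_fuzzy_cloud(scan, sc, cyl)

  o <- cylinder_objective(cyl, fc, cyl, t = 200)
  expect_equal(o$normalized, 1, tolerance = 1e-12)
  expect_true(all(o$per_point >= 0))

  # truth beats an inflated radius on near-noiseless surface points
  inflated <- cylinder_geometry(cyl$radius * 1.2, cyl$azimuth, cyl$elevation,
                                cyl$center, cyl$length)
  expect_lt(cylinder_objective(cyl, fc, cyl, t = 200)$mean,
            cylinder_objective(inflated, fc, cyl, t = 200)$mean)

  # duplicating every point leaves the normalized objective unchanged
  dup <- scan[rep(seq_len(nrow(scan)), 2), ]
  fc2 <- make_fuzzy_cloud(dup, sc, cyl)
  expect_equal(cylinder_objective(inflated, fc2, cyl, t = 200)$normalized,
               cylinder_objective(inflated, fc, cyl, t = 200)$normalized,
               tolerance = 1e-12)
})

test_that("objective is invariant under rigid motion and global rescaling", {
  cyl <- ref_truth()
  sc <- ref_scanner(50)
  scan <- simulate_tls_scan(cyl, sc)
  fc <- make_fuzzy_cloud(scan, sc, cyl)
  probe <- cylinder_geometry(0.053, 0.01, pi / 2 - 0.02, c(0.002, -0.001, 0),
                             cyl$length)
  v0 <- cylinder_objective(probe, fc, cyl, t = 300)$normalized

  move_scene <- function(R, shift) {
    move_cyl <- function(g) {
      ang <- axis_angles(as.numeric(R %*% g$axis))
      cylinder_geometry(g$radius, ang[1], ang[2],
                        as.numeric(R %*% g$center) + shift, g$length)
    }
    fc_r <- fc
    fc_r$mean <- t(R %*% t(fc$mean) + shift)
    fc_r$cov <- t(vapply(seq_len(nrow(fc$mean)), function(i) {
      S <- R %*% fuzzycyl:::point_covariance(fc, i) %*% t(R)
      S[c(1, 2, 3, 5, 6, 9)]
    }, numeric(6)))
    list(probe = move_cyl(probe), fc = fc_r, cyl0 = move_cyl(cyl))
  }
  rot_about <- function(u, a) {
    u <- u / sqrt(sum(u^2))
    K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
    diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  }

  # translations and rotations about the basis reference vector are exact
  # (tangent-point angles are tied to the in-plane basis, which co-rotates)
  set.seed(141)
  for (i in 1:3) {
    m <- move_scene(rot_about(c(0, 1, 0), stats::runif(1, -0.3, 0.3)),
                    stats::rnorm(3))
    expect_equal(cylinder_objective(m$probe, m$fc, m$cyl0, t = 300)$normalized,
                 v0, tolerance = 1e-8)
  }
  # a general rotation re-seats the tangent lines; the residual discrepancy
  # is envelope discretization and vanishes as the envelope grows
  R <- random_rotation3()
  dev_t <- vapply(c(100, 400, 1600), function(t) {
    m <- move_scene(R, c(0, 0, 0))
    abs(cylinder_objective(m$probe, m$fc, m$cyl0, t = t)$normalized -
          cylinder_objective(probe, fc, cyl, t = t)$normalized)
  }, numeric(1))
  expect_true(all(diff(dev_t) < 0))
  expect_lt(dev_t[3], 1e-3)

  for (s in c(0.1, 10)) {
    fc_s <- fc
    fc_s$mean <- s * fc$mean
    fc_s$cov <- s^2 * fc$cov
    scale_cyl <- function(g) cylinder_geometry(s * g$radius, g$azimuth,
                                               g$elevation, s * g$center,
                                               s * g$length)
    expect_equal(cylinder_objective(scale_cyl(probe), fc_s, scale_cyl(cyl),
                                    t = 300)$normalized,
                 v0, tolerance = 1e-8)
  }
})
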