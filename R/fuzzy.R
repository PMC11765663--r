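#' Build a fuzzy point cloud
#'
#' Replaces each measured point by a trivariate Gaussian whose covariance
#' is given by the LiDAR noise model ([build_covariance()]) evaluated at
#' the point under a *geometry estimate*: the covariance depends both on
#' the point (range, beam direction) and on the cylinder (incidence
#' angle), which is the circular dependence the outer fitting loop breaks
#' iteratively. Points whose covariance construction fails (degenerate,
#' e.g. on the axis) are dropped with a warning rather than failing the
#' whole cloud.
#'
#' @param points data.frame with `x`, `y`, `z` and optionally `scanner_id`
#'   columns (as produced by [simulate_tls_scan()]), or an n-by-3 matrix.
#' @param scanners list of [scanner_spec()] (or a single one); matched to
#'   points by `scanner_id`.
#' @param cyl the [cylinder_geometry()] estimate used for incidence angles.
#' @return object of class `"fuzzy_point_cloud"`: list with `mean` (n x 3),
#'   `cov` (n x 6 matrix of the unique covariance entries, columns
#'   xx, xy, xz, yy, yz, zz), `scanner_id`, and `geometry_used`.
#' @export
make_fuzzy_cloud <- function(points, scanners, cyl) {
  pts <- as_point_df(points)
  if (inherits(scanners, "scanner_spec")) scanners <- list(scanners)
  ids <- vapply(scanners, function(s) s$id, integer(1))
  n <- nrow(pts)
  if (n < 1L) stop("empty cloud")
  mean_m <- as.matrix(pts[, c("x", "y", "z")])
  cov_m <- matrix(NA_real_, n, 6)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    sc <- scanners[[match(pts$scanner_id[i], ids)]]
    S <- try(build_covariance(mean_m[i, ], sc, cyl), silent = TRUE)
    if (inherits(S, "try-error")) {
      ok[i] <- FALSE
    } else {
      cov_m[i, ] <- S[c(1, 2, 3, 5, 6, 9)]
    }
  }
  if (!all(ok)) {
    warning(sprintf("dropped %d point(s) with degenerate covariance", sum(!ok)))
  }
  if (!any(ok)) stop("empty cloud: all points degenerate")
  structure(
    list(mean = mean_m[ok, , drop = FALSE], cov = cov_m[ok, , drop = FALSE],
         scanner_id = pts$scanner_id[ok], geometry_used = cyl),
    class = "fuzzy_point_cloud")
}

#' @export
print.fuzzy_point_cloud <- function(x, ...) {
  cat(sprintf("Fuzzy point cloud: %d Gaussian points, %d scanner(s)\n",
              nrow(x$mean), length(unique(x$scanner_id))))
  cat(sprintf("  built from geometry estimate with r = %.6g m\n",
              x$geometry_used$radius))
  invisible(x)
}

# full 3x3 covariance of point i
point_covariance <- function(fc, i) {
  s <- fc$cov[i, ]
  matrix(s[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
}

#' Sample a replicate point cloud from a fuzzy point cloud
#'
#' Draws one point from each member Gaussian, preserving scanner ids.
#' Deterministic given the seed; the Monte-Carlo study derives one child
#' seed per replicate (see [child_seed()]) so any replicate is
#' reproducible in isolation.
#'
#' @param fc a [make_fuzzy_cloud()] result.
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `z`, `scanner_id`.
#' @export
sample_replicate <- function(fc, seed) {
  set.seed(as.integer(seed))
  n <- nrow(fc$mean)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  out <- fc$mean
  for (i in seq_len(n)) {
    L <- chol(point_covariance(fc, i))
    out[i, ] <- out[i, ] + as.numeric(z[i, ] %*% L)
  }
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
             scanner_id = fc$scanner_id)
}

#' Per-replicate child seeds
#'
#' Deterministic counter scheme deriving the seed of replicate `k` from a
#' master seed: `(master mod 1e5) * 20011 + k`, which stays below 2^31 for
#' k up to ~1e5. Replicate k of a larger study equals replicate k of a
#' smaller one under the same master seed.
#'
#' @param master integer master seed.
#' @param k replicate index (1-based).
#' @return integer seed.
#' @export
child_seed <- function(master, k) {
  as.integer((as.integer(master) %% 100000L) * 20011L + as.integer(k))
}

#' Whitening transform of a Gaussian
#'
#' Builds the affine map `T(x) = Lambda^(-1/2) U' (x - mu)` (with
#' `Sigma = U Lambda U'` the eigendecomposition) sending the Gaussian to
#' the standard normal. Mahalanobis distances under the Gaussian equal
#' Euclidean distances after `T`. The eigendecomposition (rather than a
#' triangular factor) is used so the principal-axis frame is available
#' directly; ties and signs are fixed deterministically (eigenvalues in
#' decreasing order, first nonzero eigenvector component positive).
#'
#' @param mean Gaussian mean (any dimension).
#' @param cov covariance matrix.
#' @return list with `forward` and `inverse` functions, the matrix `W`
#'   (`T(x) = W %*% (x - mean)`), `Winv`, `mean`, and the principal
#'   standard deviations `sdev`.
#' @export
whitening_transform <- function(mean, cov) {
  mean <- as.numeric(mean)
  S <- as.matrix(cov)
  check_spd(S, "covariance")
  e <- eigen(S, symmetric = TRUE)
  if (e$values[length(e$values)] <= 0 ||
      e$values[1] / e$values[length(e$values)] > 1e12) {
    stop("ill-conditioned covariance: condition number exceeds 1e12")
  }
  U <- if (e$values[1] / e$values[length(e$values)] - 1 < 1e-10) {
    diag(length(mean))  # isotropic: any frame whitens; pick the identity
  } else {
    apply(e$vectors, 2, function(u) {
      j <- which(abs(u) > 1e-12)[1]
      if (u[j] < 0) -u else u
    })
  }
  W <- diag(1 / sqrt(e$values), length(mean)) %*% t(U)
  Winv <- U %*% diag(sqrt(e$values), length(mean))
  list(
    forward = function(x) {
      if (is.matrix(x)) t(W %*% (t(x) - mean)) else as.numeric(W %*% (x - mean))
    },
    inverse = function(y) {
      if (is.matrix(y)) t(Winv %*% t(y) + mean) else as.numeric(Winv %*% y + mean)
    },
    W = W, Winv = Winv, mean = mean, sdev = sqrt(e$values))
}

as_point_df <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 3L)
    points <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3])
  }
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (is.null(points$scanner_id)) points$scanner_id <- 0L
  points
}
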