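# Internal parameterization used by all optimizers:
# par = (r, azimuth, elevation, c1, c2), where the 3D center is
# p0 + c1*e1 + c2*e2 with (e1, e2) the cross-section basis of the current
# axis and p0 a fixed anchor point. The along-axis component of the center
# is thereby excluded from the search: it is unidentifiable from the
# objective (the fitted shape is invariant along the axis).
par_to_geometry <- function(par, p0, length = Inf) {
  v <- axis_vector(par[2], par[3])
  B <- cross_section_basis(v)
  center <- p0 + par[4] * B[1, ] + par[5] * B[2, ]
  cylinder_geometry(par[1], par[2], par[3], center, length)
}

geometry_to_par <- function(cyl, p0) {
  B <- cross_section_basis(cyl$axis)
  d <- cyl$center - p0
  c(cyl$radius, cyl$azimuth, cyl$elevation,
    sum(d * B[1, ]), sum(d * B[2, ]))
}

# orthogonal distances of points to the cylinder surface (signed: d - r)
cylinder_residuals <- function(par, X, p0) {
  v <- axis_vector(par[2], par[3])
  B <- cross_section_basis(v)
  center <- p0 + par[4] * B[1, ] + par[5] * B[2, ]
  w <- sweep(X, 2, center)
  wv <- as.numeric(w %*% v)
  sqrt(pmax(rowSums(w^2) - wv^2, 0)) - par[1]
}

# initial geometry: axis from the principal eigenvector of the point
# covariance (assumes the scanned patch is longer along the axis than
# across it -- documented limitation for stubby cylinders), then an
# algebraic (Kasa) circle fit in the projected plane.
initial_geometry <- function(X) {
  ctr <- colMeans(X)
  e <- eigen(stats::cov(X), symmetric = TRUE)
  v <- e$vectors[, 1]
  j <- which(abs(v) > 1e-12)[1]
  if (v[j] < 0) v <- -v
  ang <- axis_angles(v)
  B <- cross_section_basis(v)
  P2 <- sweep(X, 2, ctr) %*% t(B)
  # Kasa: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(P2[, 1], P2[, 2], 1)
  b <- -(P2[, 1]^2 + P2[, 2]^2)
  sol <- qr.solve(A, b)
  cc <- c(-sol[1] / 2, -sol[2] / 2)
  r0 <- sqrt(max(sum(cc^2) - sol[3], 1e-8))
  center <- ctr + cc[1] * B[1, ] + cc[2] * B[2, ]
  cylinder_geometry(r0, ang[1], ang[2], center)
}

#' Euclidean least-squares cylinder fit (Gauss-Newton)
#'
#' Minimizes the sum of squared orthogonal distances between the points
#' and the cylinder surface with a damped Gauss-Newton iteration
#' (numerical Jacobian, multiplicative step backtracking when a step
#' would increase the residual). Initialized from the principal axis of
#' the point covariance and a Kasa circle fit unless `init` is given.
#'
#' @param points data.frame / matrix of 3D points (see [make_fuzzy_cloud()]).
#' @param init optional [cylinder_geometry()] starting value.
#' @param max_iter maximum Gauss-Newton steps.
#' @param grad_tol convergence threshold on the residual gradient norm.
#' @return a `"cylinder_fit"` object (see [fit_cylinder()]).
#' @export
els_fit <- function(points, init = NULL, max_iter = 100, grad_tol = 1e-8) {
  pts <- as_point_df(points)
  X <- as.matrix(pts[, c("x", "y", "z")])
  if (nrow(X) < 6L) stop("fit failure: need at least 6 points")
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[2] < 1e-12 * max(sv[1], 1)) stop("fit failure: points are collinear")
  g0 <- if (is.null(init)) initial_geometry(X) else init
  p0 <- g0$center
  par <- geometry_to_par(g0, p0)
  res <- cylinder_residuals(par, X, p0)
  ssr <- sum(res^2)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    J <- num_jacobian(function(p) cylinder_residuals(p, X, p0), par)
    g <- 2 * crossprod(J, res)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    step <- try(qr.solve(J, -res), silent = TRUE)
    if (inherits(step, "try-error")) {
      step <- try(solve(crossprod(J) + 1e-8 * diag(5), -crossprod(J, res)),
                  silent = TRUE)
      if (inherits(step, "try-error")) {
        stop("fit failure: rank-deficient Jacobian")
      }
      step <- as.numeric(step)
    }
    lam <- 1
    improved <- FALSE
    for (k in seq_len(40)) {
      cand <- par + lam * step
      if (cand[1] > 1e-6) {
        res_c <- cylinder_residuals(cand, X, p0)
        ssr_c <- sum(res_c^2)
        if (is.finite(ssr_c) && ssr_c <= ssr) {
          par <- cand; res <- res_c
          improved <- TRUE
          if (ssr - ssr_c < 1e-16 * (ssr + 1e-300)) { converged <- TRUE }
          ssr <- ssr_c
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  geom <- par_to_geometry(par, p0)
  new_cylinder_fit(geom, method = "ELS", objective = ssr,
                   converged = converged, iterations = it,
                   residuals = res, points = X,
                   scanner_id = pts$scanner_id)
}

num_jacobian <- function(f, par, h = 1e-7) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    hp <- h * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + hp
    pm <- par; pm[j] <- pm[j] - hp
    J[, j] <- (f(pp) - f(pm)) / (2 * hp)
  }
  J
}

#' RANSAC + Euclidean least-squares cylinder fit
#'
#' Robustified least squares: fits up to `max_subsets` random minimal
#' subsets of 9 points with [els_fit()], selects the candidate model with
#' the smallest median squared residual over the full cloud (least median
#' of squares -- robust to up to half the points being outliers and free
#' of a noise-scale parameter), declares inliers within 2.5 robust
#' standard deviations (`1.4826 * sqrt(median squared residual)`) of the
#' winning model, and refits the inlier set with Gauss-Newton.
#'
#' @inheritParams els_fit
#' @param max_subsets maximum number of random minimal subsets (default 100).
#' @param subset_size minimal subset size (default 9).
#' @param seed integer seed for subset selection.
#' @return a `"cylinder_fit"` object with method `"RELS"`.
#' @export
ransac_els_fit <- function(points, max_subsets = 100, subset_size = 9,
                           seed = 1, max_iter = 100) {
  pts <- as_point_df(points)
  n <- nrow(pts)
  if (n < subset_size) stop("fit failure: fewer points than the RANSAC subset size")
  full <- els_fit(pts, max_iter = max_iter)
  X <- as.matrix(pts[, c("x", "y", "z")])
  set.seed(as.integer(seed))
  best <- NULL
  for (k in seq_len(max_subsets)) {
    idx <- sample.int(n, subset_size)
    # each minimal subset self-initializes; a contaminated global init
    # would drag every candidate toward the same corrupted optimum
    cand <- try(els_fit(pts[idx, , drop = FALSE], max_iter = 50),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    res_all <- cylinder_residuals(
      geometry_to_par(cand$geometry, cand$geometry$center), X,
      cand$geometry$center)
    score <- stats::median(res_all^2)
    if (is.finite(score) && (is.null(best) || score < best$score)) {
      best <- list(score = score, res = res_all, geom = cand$geometry)
    }
  }
  if (is.null(best)) stop("fit failure: no valid RANSAC consensus")
  sigma_hat <- 1.4826 * sqrt(best$score)
  inl <- abs(best$res) <= max(2.5 * sigma_hat, 1e-12)
  if (sum(inl) < 6) stop("fit failure: no valid RANSAC consensus")
  out <- els_fit(pts[inl, , drop = FALSE], init = best$geom,
                 max_iter = max_iter)
  out$method <- "RELS"
  out$inliers <- which(inl)
  out$points <- X
  out$scanner_id <- pts$scanner_id
  out
}

#' Minimize the fuzzy envelope objective for a fixed fuzzy cloud
#'
#' Inner optimization of the expected-Mahalanobis fitting pipeline:
#' minimizes [cylinder_objective()] over (radius, azimuth, elevation, 2D
#' center) with a bounded quasi-Newton method (`optim`, L-BFGS-B; bound
#' r >= 1e-4 m) while the fuzzy cloud's covariances stay fixed. Never
#' returns a geometry whose normalized objective exceeds the
#' initialization's.
#'
#' @param fc a [make_fuzzy_cloud()] result.
#' @param init initial [cylinder_geometry()].
#' @param t number of tangent lines.
#' @param weighting see [envelope_expected_sq()].
#' @param control passed to [stats::optim()] (merged over defaults).
#' @return a `"cylinder_fit"` object with method `"EM"`.
#' @export
em_optimize <- function(fc, init, t = 1000,
                        weighting = c("normalized", "unnormalized"),
                        control = list()) {
  weighting <- match.arg(weighting)
  p0 <- init$center
  par0 <- geometry_to_par(init, p0)
  norm0 <- mean(.objective_per_point(init, fc, t, weighting))
  fn <- function(par) {
    g <- try(par_to_geometry(par, p0), silent = TRUE)
    if (inherits(g, "try-error")) return(1e10)
    val <- mean(.objective_per_point(g, fc, t, weighting)) / norm0
    if (!is.finite(val)) 1e10 else val
  }
  ctl <- utils::modifyList(
    list(maxit = 200, factr = 1e7,
         parscale = c(max(par0[1], 1e-3), 0.1, 0.1,
                      max(par0[1], 1e-3), max(par0[1], 1e-3)),
         ndeps = rep(1e-5, 5)),
    control)
  opt <- try(stats::optim(par0, fn, method = "L-BFGS-B",
                          lower = c(1e-4, -Inf, -Inf, -Inf, -Inf),
                          control = ctl),
             silent = TRUE)
  if (inherits(opt, "try-error")) {
    stop("fit failure: envelope objective optimizer failed from the given start")
  }
  par <- if (opt$value <= 1) opt$par else par0
  geom <- par_to_geometry(par, p0)
  new_cylinder_fit(geom, method = "EM",
                   objective = min(opt$value, 1),
                   converged = opt$convergence == 0,
                   iterations = opt$counts[1],
                   residuals = NULL, points = fc$mean,
                   scanner_id = fc$scanner_id)
}

# max relative geometry change: r, cross-axis center (scaled by r), axis angle
geometry_change <- function(g_new, g_old) {
  r <- g_old$radius
  dc <- g_new$center - g_old$center
  dc_perp <- dc - sum(dc * g_old$axis) * g_old$axis
  ang <- acos(min(1, abs(sum(g_new$axis * g_old$axis))))
  max(abs(g_new$radius - r) / r, max(abs(dc_perp)) / r, ang)
}

#' Full fuzzy cylinder fitting loop
#'
#' The complete expected-Mahalanobis pipeline: (1) initial geometry by
#' Euclidean least squares (or RANSAC for `method = "rem"`); (2) build a
#' fuzzy point cloud from the current geometry estimate; (3) minimize the
#' envelope objective ([em_optimize()]); (4) if the geometry changed more
#' than `tol` and fewer than `max_updates` covariance updates were done,
#' return to (2). Convergence of the covariance-update loop is not
#' guaranteed in general; the last iterate is returned with
#' `converged = FALSE` in that case.
#'
#' @param points point data.frame (with `scanner_id`) or matrix.
#' @param scanners list of [scanner_spec()].
#' @param method `"em"` (ELS initialization) or `"rem"` (RANSAC).
#' @param t number of tangent lines.
#' @param max_updates maximum covariance updates (default 10).
#' @param tol outer-loop convergence threshold on the relative geometry
#'   change (default 1e-3).
#' @param weighting see [envelope_expected_sq()].
#' @param seed seed for the RANSAC stage (rem only).
#' @return a `"cylinder_fit"` object; `$trace` holds one geometry per
#'   outer iteration, `$outer_iterations` the number of covariance
#'   updates performed.
#' @export
fuzzy_fit_loop <- function(points, scanners, method = c("em", "rem"),
                           t = 1000, max_updates = 10, tol = 1e-3,
                           weighting = "normalized", seed = 1) {
  method <- match.arg(method)
  pts <- as_point_df(points)
  base <- if (method == "rem") ransac_els_fit(pts, seed = seed) else els_fit(pts)
  geom <- base$geometry
  anchor <- geom$center
  trace <- list(geom)
  converged <- FALSE
  k <- 0L
  fit <- NULL
  for (k in seq_len(max_updates)) {
    fc <- make_fuzzy_cloud(pts, scanners, geom)
    fit <- em_optimize(fc, geom, t = t, weighting = weighting)
    g_new <- fit$geometry
    # pin the unidentifiable along-axis center position to the anchor
    g_new$center <- g_new$center +
      sum((anchor - g_new$center) * g_new$axis) * g_new$axis
    delta <- geometry_change(g_new, geom)
    geom <- g_new
    trace[[length(trace) + 1L]] <- geom
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- new_cylinder_fit(geom, method = toupper(method),
                          objective = fit$objective,
                          converged = converged, iterations = fit$iterations,
                          residuals = NULL,
                          points = as.matrix(pts[, c("x", "y", "z")]),
                          scanner_id = pts$scanner_id)
  out$outer_iterations <- k
  out$trace <- trace
  out$init <- base$geometry
  out$residuals <- cylinder_residuals(
    geometry_to_par(geom, geom$center),
    out$points, geom$center)
  out
}

new_cylinder_fit <- function(geometry, method, objective, converged,
                             iterations, residuals, points, scanner_id) {
  structure(
    list(geometry = geometry, method = method,
         objective = objective, converged = converged,
         iterations = as.integer(iterations),
         outer_iterations = NA_integer_,
         residuals = residuals, points = points,
         scanner_id = scanner_id, trace = NULL),
    class = "cylinder_fit")
}
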