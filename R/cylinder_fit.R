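#' Fit a cylinder to a (fuzzy) point cloud
#'
#' Front end to the four fitting methods compared by the package:
#' \describe{
#'   \item{`"els"`}{Euclidean least squares (damped Gauss-Newton) on the
#'     orthogonal distances, see [els_fit()].}
#'   \item{`"rels"`}{RANSAC-screened ELS, see [ransac_els_fit()].}
#'   \item{`"em"`}{Expected-Mahalanobis envelope fitting on the fuzzy
#'     point cloud, initialized by ELS, with iterative covariance
#'     updates, see [fuzzy_fit_loop()].}
#'   \item{`"rem"`}{Same, initialized by RANSAC + ELS.}
#' }
#' The `"em"`/`"rem"` methods need scanner specifications to build the
#' per-point covariances of the fuzzy cloud.
#'
#' @param points data.frame with columns `x`, `y`, `z` and optionally
#'   `scanner_id`, or an n-by-3 matrix.
#' @param method one of `"els"`, `"rels"`, `"em"`, `"rem"`.
#' @param scanners list of [scanner_spec()] (required for em/rem).
#' @param t number of tangent lines in the envelope objective.
#' @param max_updates maximum covariance updates of the outer loop.
#' @param seed seed for the RANSAC stage.
#' @param ... further arguments passed to the underlying fitter.
#' @return object of class `"cylinder_fit"` with components `geometry`
#'   (a [cylinder_geometry()]), `method`, `objective` (residual sum of
#'   squares for els/rels; normalized envelope objective for em/rem),
#'   `converged`,
#'   `iterations`, `outer_iterations`, `residuals` (orthogonal signed
#'   distances to the fitted surface, meters), `points`, `scanner_id`,
#'   and for em/rem `trace` (per-update geometry snapshots) and `init`.
#' @examples
#' truth <- cylinder_geometry(0.05, 0, pi / 2, c(0, 0, 0), 0.25)
#' sc <- scanner_spec(c(0, 50, 0), angular_step = 0.05 * pi / 180)
#' scan <- simulate_tls_scan(truth, sc)
#' fit <- fit_cylinder(scan, method = "els")
#' coef(fit)
#' @export
fit_cylinder <- function(points, method = c("els", "rels", "em", "rem"),
                         scanners = NULL, t = 1000, max_updates = 10,
                         seed = 1, ...) {
  method <- match.arg(method)
  if (method %in% c("em", "rem") && is.null(scanners)) {
    stop("methods 'em' and 'rem' require scanner specifications")
  }
  fit <- switch(method,
    els = els_fit(points, ...),
    rels = ransac_els_fit(points, seed = seed, ...),
    em = fuzzy_fit_loop(points, scanners, method = "em", t = t,
                        max_updates = max_updates, seed = seed, ...),
    rem = fuzzy_fit_loop(points, scanners, method = "rem", t = t,
                         max_updates = max_updates, seed = seed, ...))
  fit$scanners <- scanners
  fit$call <- match.call()
  fit
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("Cylinder fit (%s)%s\n", x$method,
              if (isTRUE(x$converged)) "" else "  [not converged]"))
  print(x$geometry)
  if (!is.na(x$outer_iterations)) {
    cat(sprintf("  covariance updates: %d\n", x$outer_iterations))
  }
  cat(sprintf("  objective: %.6g,  n = %d points\n",
              x$objective, nrow(x$points)))
  invisible(x)
}

#' @export
coef.cylinder_fit <- function(object, ...) {
  g <- object$geometry
  c(radius = g$radius, azimuth = g$azimuth, elevation = g$elevation,
    center_x = g$center[1], center_y = g$center[2], center_z = g$center[3])
}

#' @export
residuals.cylinder_fit <- function(object, ...) {
  if (is.null(object$residuals)) {
    g <- object$geometry
    cylinder_residuals(geometry_to_par(g, g$center), object$points, g$center)
  } else {
    object$residuals
  }
}

#' @export
summary.cylinder_fit <- function(object, ...) {
  r <- residuals(object)
  out <- list(fit = object,
              rmse = sqrt(mean(r^2)),
              resid_quartiles = stats::quantile(r, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.cylinder_fit"
  out
}

#' @export
print.summary.cylinder_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: %.4g m\n", x$rmse))
  cat("  residual quartiles (m):\n")
  print(signif(x$resid_quartiles, 4))
  invisible(x)
}

#' Signed orthogonal distance of new points to a fitted cylinder
#'
#' @param object a `"cylinder_fit"`.
#' @param newdata points (data.frame with x/y/z or n-by-3 matrix);
#'   defaults to the fitting data.
#' @param ... unused.
#' @return numeric vector of signed distances to the fitted surface
#'   (positive outside), meters.
#' @export
predict.cylinder_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$points else {
    as.matrix(as_point_df(newdata)[, c("x", "y", "z")])
  }
  g <- object$geometry
  cylinder_residuals(geometry_to_par(g, g$center), X, g$center)
}

#' Sample replicate point clouds from a fitted cylinder's noise model
#'
#' Builds the fuzzy point cloud implied by the fitted geometry and the
#' stored scanner specifications and draws `nsim` replicate clouds.
#'
#' @param object a `"cylinder_fit"` produced with scanners available.
#' @param nsim number of replicate clouds.
#' @param seed master seed (child seeds per replicate).
#' @param ... unused.
#' @return list of `nsim` data.frames (`x`, `y`, `z`, `scanner_id`).
#' @export
simulate.cylinder_fit <- function(object, nsim = 1, seed = 1, ...) {
  if (is.null(object$scanners)) {
    stop("simulate() needs a fit created with scanner specifications")
  }
  df <- data.frame(x = object$points[, 1], y = object$points[, 2],
                   z = object$points[, 3], scanner_id = object$scanner_id)
  fc <- make_fuzzy_cloud(df, object$scanners, object$geometry)
  lapply(seq_len(nsim), function(k) sample_replicate(fc, child_seed(seed, k)))
}

#' Cross-section plot of a cylinder fit
#'
#' Scatter of the points projected onto the fitted cross-section plane,
#' with the fitted circle overlaid.
#'
#' @param x a `"cylinder_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cylinder_fit <- function(x, ...) {
  g <- x$geometry
  P2 <- project_to_cross_section(x$points, g)
  cQ <- as.numeric(project_to_cross_section(matrix(g$center, 1), g))
  graphics::plot(P2[, 1], P2[, 2], asp = 1, pch = 16, cex = 0.5,
                 col = "grey40", xlab = "e1 (m)", ylab = "e2 (m)",
                 main = sprintf("Cylinder cross-section (%s fit)", x$method),
                 ...)
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cQ[1] + g$radius * cos(th), cQ[2] + g$radius * sin(th),
                  col = "red3", lwd = 2)
  graphics::points(cQ[1], cQ[2], pch = 3, col = "red3")
  invisible(x)
}
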