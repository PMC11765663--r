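#' Mahalanobis distance
#'
#' `sqrt((x - y)' P (x - y))` with `P` a symmetric positive-definite
#' precision (inverse covariance) matrix. Unitless, scale-invariant, and
#' anisotropy-aware; equals the Euclidean distance when `P` is the
#' identity.
#'
#' @param x,y numeric vectors of equal length.
#' @param precision precision matrix.
#' @return nonnegative scalar.
#' @export
mahalanobis_distance <- function(x, y, precision) {
  P <- as.matrix(precision)
  check_spd(P, "precision")
  d <- as.numeric(x) - as.numeric(y)
  sqrt(max(0, sum(d * (P %*% d))))
}

#' Mahalanobis distance from a Gaussian mean to a tangent line
#'
#' Evaluated in the frame whose origin is the circle center and whose axes
#' are the Gaussian's principal axes (standard deviations `sd`): for a
#' tangent point `cp` on the circle, the tangent line is
#' `{x : <cp, x - cp> = 0}` and
#' `tau = |cx (cx - mx) + cy (cy - my)| / sqrt(sx^2 cx^2 + sy^2 cy^2)`.
#' Both the numerator (`<cp, cp - mu>`) and the denominator
#' (`sqrt(cp' Sigma cp)`) are frame-invariant, so the same value can be
#' computed in any frame centered at the circle center.
#'
#' @param cp length-2 tangent point (circle-centered frame).
#' @param mean length-2 Gaussian mean (same frame).
#' @param sd length-2 principal standard deviations, > 0.
#' @return nonnegative scalar `tau`.
#' @export
tangent_tau <- function(cp, mean, sd) {
  cp <- as.numeric(cp); mean <- as.numeric(mean); sd <- as.numeric(sd)
  stopifnot(all(sd > 0))
  if (sum(cp^2) == 0) stop("degenerate line: tangent point at the circle center")
  abs(sum(cp * (cp - mean))) / sqrt(sum(sd^2 * cp^2))
}

#' Expected squared Mahalanobis distance to one tangent line
#'
#' Closed form `tau^2 + 1`: after whitening, the signed distance of a
#' standard-normal sample to the line is Gaussian with mean `tau` and unit
#' variance, so its second moment is `tau^2 + 1`.
#'
#' @param tau nonnegative line distance from [tangent_tau()].
#' @return `tau^2 + 1`.
#' @export
expected_sq_line <- function(tau) {
  stopifnot(all(tau >= 0))
  tau^2 + 1
}

#' Expected squared Mahalanobis distance to a circle via its envelope
#'
#' Aggregates the per-line expectations over the tangent-line envelope,
#' weighting each line by the inverse cubed Mahalanobis distance of its
#' tangent point to the distribution so that far-away lines contribute
#' little. Two aggregation conventions are provided: `"normalized"`
#' (default) divides the weighted sum by the sum of the weights, yielding
#' a weighted mean of `tau_i^2 + 1` that attains its minimum when the
#' distribution lies on the circle; `"unnormalized"` divides by the number
#' of lines `t` instead. The normalized form is the default because the
#' unnormalized one decreases monotonically as the circle moves away from
#' the distribution and therefore cannot serve as a fitting objective on
#' its own (see the methods vignette).
#'
#' @param mean length-2 Gaussian mean.
#' @param cov 2x2 covariance.
#' @param center length-2 circle center.
#' @param radius circle radius, > 0.
#' @param t number of tangent lines, >= 3.
#' @param weighting `"normalized"` or `"unnormalized"`.
#' @param eps guard on the Mahalanobis distance in the weight denominator.
#' @return nonnegative scalar.
#' @export
envelope_expected_sq <- function(mean, cov, center, radius, t = 1000,
                                 weighting = c("normalized", "unnormalized"),
                                 eps = 1e-6) {
  weighting <- match.arg(weighting)
  if (t < 3) stop("envelope too small: need at least 3 tangent lines")
  S <- as.matrix(cov)
  check_spd(S, "covariance")
  mu <- as.numeric(mean) - as.numeric(center)
  .envelope_values(matrix(mu, 1), S[1, 1], S[1, 2], S[2, 2],
                   radius, t, weighting, eps)
}

# Vectorized evaluation over n points.
# mu: n x 2 means relative to the circle center; a, b, cc: per-point 2x2
# covariance entries [a b; b cc]. Returns n per-point envelope values.
.envelope_values <- function(mu, a, b, cc, radius, t, weighting, eps) {
  theta <- 2 * pi * (seq_len(t) - 1) / t
  ct <- cos(theta); st <- sin(theta)
  r <- radius
  # tau^2 = <cp, cp - mu>^2 / (cp' Sigma cp), cp = r (ct, st)
  num <- r^2 - r * (outer(mu[, 1], ct) + outer(mu[, 2], st))
  den <- r^2 * (outer(a, ct^2) + 2 * outer(b, ct * st) + outer(cc, st^2))
  tau2 <- num^2 / den
  # M^2(cp | mu, Sigma) = (cp - mu)' Sigma^-1 (cp - mu)
  dx <- outer(rep(r, nrow(mu)), ct) - mu[, 1]
  dy <- outer(rep(r, nrow(mu)), st) - mu[, 2]
  det <- a * cc - b^2
  M2 <- (cc * dx^2 - 2 * b * dx * dy + a * dy^2) / det
  M <- pmax(sqrt(M2), eps)
  w <- 1 / M^3
  if (weighting == "normalized") {
    rowSums((tau2 + 1) * w) / rowSums(w)
  } else {
    rowSums((tau2 + 1) * w) / t
  }
}

#' Fuzzy cylinder objective
#'
#' The mean, over the fuzzy point cloud, of the expected squared
#' Mahalanobis distance from each (cross-section-projected) Gaussian to
#' the candidate cylinder's cross-section circle, approximated by its
#' tangent-line envelope; normalized by the same quantity evaluated at a
#' reference geometry `cyl0` (typically the initial estimate) so that
#' values are comparable across clouds and noise levels and equal 1 at
#' `cyl0`.
#'
#' @param cyl candidate [cylinder_geometry()].
#' @param fc a [make_fuzzy_cloud()] result.
#' @param cyl0 reference geometry for normalization.
#' @param t number of tangent lines.
#' @param weighting see [envelope_expected_sq()].
#' @return object of class `"objective_breakdown"`: list with
#'   `per_point`, `mean`, `normalizer`, `normalized`.
#' @export
cylinder_objective <- function(cyl, fc, cyl0 = cyl, t = 1000,
                               weighting = c("normalized", "unnormalized")) {
  weighting <- match.arg(weighting)
  if (nrow(fc$mean) < 1L) stop("empty cloud")
  per <- .objective_per_point(cyl, fc, t, weighting)
  per0 <- .objective_per_point(cyl0, fc, t, weighting)
  structure(
    list(per_point = per, mean = mean(per),
         normalizer = mean(per0), normalized = mean(per) / mean(per0)),
    class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("Fuzzy cylinder objective: mean %.6g, normalized %.6g (n = %d)\n",
              x$mean, x$normalized, length(x$per_point)))
  invisible(x)
}

# per-point envelope values for a candidate geometry (fast path)
.objective_per_point <- function(cyl, fc, t, weighting, eps = 1e-6) {
  B <- cross_section_basis(cyl$axis)
  e1 <- B[1, ]; e2 <- B[2, ]
  rel <- sweep(fc$mean, 2, cyl$center)
  mu <- cbind(as.numeric(rel %*% e1), as.numeric(rel %*% e2))
  # projected covariance entries: a = e1' S e1, b = e1' S e2, cc = e2' S e2
  C <- fc$cov  # columns xx, xy, xz, yy, yz, zz
  quad <- function(u, v) {
    C[, 1] * u[1] * v[1] + C[, 4] * u[2] * v[2] + C[, 6] * u[3] * v[3] +
      C[, 2] * (u[1] * v[2] + u[2] * v[1]) +
      C[, 3] * (u[1] * v[3] + u[3] * v[1]) +
      C[, 5] * (u[2] * v[3] + u[3] * v[2])
  }
  .envelope_values(mu, quad(e1, e1), quad(e1, e2), quad(e2, e2),
                   cyl$radius, t, weighting, eps)
}
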