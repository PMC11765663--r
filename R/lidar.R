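#' Terrestrial laser scanner specification
#'
#' Beam and noise parameters of a fixed-position LiDAR instrument. The
#' defaults approximate a phase-shift survey scanner of the Faro Focus
#' class, derived from manufacturer datasheet figures (exit beam diameter
#' 2.12 mm, beam divergence half-angle 0.15 mrad, ~1 mm base range
#' uncertainty), scanning at half the finest angular resolution
#' (0.018 degrees). They are configurable approximations, not measured
#' constants.
#'
#' @param position length-3 scanner location, meters.
#' @param exit_diameter beam diameter at the exit aperture (m).
#' @param divergence_half_angle beam divergence half-angle (rad).
#' @param base_range_sigma base-level range uncertainty (m), > 0.
#' @param angular_step scan grid spacing (rad).
#' @param id integer scanner identifier.
#' @return object of class `"scanner_spec"`.
#' @export
scanner_spec <- function(position,
                         exit_diameter = 2.12e-3,
                         divergence_half_angle = 0.15e-3,
                         base_range_sigma = 1.0e-3,
                         angular_step = 0.018 * pi / 180,
                         id = 0L) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3L, all(is.finite(position)),
            exit_diameter >= 0, divergence_half_angle >= 0,
            base_range_sigma > 0, angular_step > 0)
  structure(
    list(position = position, exit_diameter = exit_diameter,
         divergence_half_angle = divergence_half_angle,
         base_range_sigma = base_range_sigma,
         angular_step = angular_step, id = as.integer(id)),
    class = "scanner_spec")
}

#' @export
print.scanner_spec <- function(x, ...) {
  cat(sprintf(
    "Scanner %d at (%.3g, %.3g, %.3g) m: d0 = %.3g mm, lambda = %.3g mrad, sigma0 = %.3g mm, step = %.4g deg\n",
    x$id, x$position[1], x$position[2], x$position[3],
    1000 * x$exit_diameter, 1000 * x$divergence_half_angle,
    1000 * x$base_range_sigma, x$angular_step * 180 / pi))
  invisible(x)
}

#' LiDAR noise model
#'
#' Per-point standard deviations of a laser range measurement.
#' `sigma_radial()` is the cross-beam uncertainty: a quarter of the beam
#' diameter (the Gaussian beam power profile is conventionally taken to
#' span four standard deviations), with the diameter growing linearly with
#' range through the divergence half-angle:
#' `d0/4 + (1/2) * range * tan(lambda)`.
#' `incidence_angle()` is the angle between the beam and the local surface
#' normal of the cylinder (the direction from the point to its projection
#' on the axis). `sigma_prop()` is the along-beam uncertainty: the base
#' range uncertainty plus the radial uncertainty smeared by the incidence
#' angle, `sigma0 + sigma_radial * tan(alpha)`, with `alpha` clamped at
#' 89.5 degrees so that grazing (silhouette) rays stay finite.
#'
#' @param mu length-3 measured point (m).
#' @param scanner a [scanner_spec()].
#' @param cyl a [cylinder_geometry()].
#' @return a length in meters (`sigma_radial`, `sigma_prop`) or an angle in
#'   radians in `[0, pi/2]` (`incidence_angle`).
#' @export
sigma_radial <- function(mu, scanner) {
  mu <- as.numeric(mu)
  R <- sqrt(sum((mu - scanner$position)^2))
  if (R == 0) stop("degenerate geometry: point coincides with the scanner")
  scanner$exit_diameter / 4 + 0.5 * R * tan(scanner$divergence_half_angle)
}

#' @rdname sigma_radial
#' @export
incidence_angle <- function(mu, scanner, cyl) {
  mu <- as.numeric(mu)
  p <- project_onto_axis(mu, cyl)
  nrm <- mu - p
  beam <- mu - scanner$position
  R <- sqrt(sum(beam^2))
  if (R == 0) stop("degenerate geometry: point coincides with the scanner")
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate geometry: point lies on the cylinder axis")
  acos(min(1, abs(sum(nrm * beam)) / (R * nn)))
}

# clamp before tan(): Eq for sigma_prop is finite only below 90 degrees
.alpha_max <- 89.5 * pi / 180

#' @rdname sigma_radial
#' @export
sigma_prop <- function(mu, scanner, cyl) {
  alpha <- min(incidence_angle(mu, scanner, cyl), .alpha_max)
  scanner$base_range_sigma + sigma_radial(mu, scanner) * tan(alpha)
}

#' Per-point measurement covariance
#'
#' Assembles the 3x3 covariance of one LiDAR point: variance
#' `sigma_prop^2` along the beam propagation direction and
#' `sigma_radial^2` in the two directions orthogonal to it, i.e.
#' `Sigma = sp^2 u u' + sr^2 (I - u u')` with `u` the unit beam direction.
#' Eigenvalues are therefore exactly `{sp^2, sr^2, sr^2}`.
#'
#' @inheritParams sigma_radial
#' @return symmetric positive-definite 3x3 matrix (m^2).
#' @export
build_covariance <- function(mu, scanner, cyl) {
  mu <- as.numeric(mu)
  beam <- mu - scanner$position
  R <- sqrt(sum(beam^2))
  if (R == 0) stop("degenerate geometry: point coincides with the scanner")
  u <- beam / R
  sr <- sigma_radial(mu, scanner)
  sp <- sigma_prop(mu, scanner, cyl)
  sp^2 * tcrossprod(u) + sr^2 * (diag(3) - tcrossprod(u))
}

#' Simulate a TLS scan of a cylinder
#'
#' Deterministic ray casting on a regular spherical grid (azimuth x polar
#' angle about the scanner, centered on the direction to the cylinder
#' center, spaced by the scanner's `angular_step`). Each grid ray is
#' intersected with the cylinder; the first (scanner-facing) intersection
#' within the cylinder's length extent is kept, so self-occlusion of the
#' back half is automatic. Hit points are noiseless surface points:
#' measurement noise enters only later, through fuzzy-cloud sampling.
#'
#' @param cyl a [cylinder_geometry()] with finite length.
#' @param scanners a [scanner_spec()] or list of them.
#' @return data.frame with columns `x`, `y`, `z` (m) and `scanner_id`.
#' @export
simulate_tls_scan <- function(cyl, scanners) {
  if (inherits(scanners, "scanner_spec")) scanners <- list(scanners)
  out <- lapply(scanners, function(sc) .scan_one(cyl, sc))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    stop("empty scan: no rays hit the cylinder")
  }
  rownames(out) <- NULL
  out
}

.scan_one <- function(cyl, sc) {
  s <- sc$position
  v <- cyl$axis
  c0 <- cyl$center
  if (sqrt(sum((s - project_onto_axis(s, cyl))^2)) <= cyl$radius) {
    stop("degenerate geometry: scanner lies inside the cylinder")
  }
  half_l <- if (is.finite(cyl$length)) cyl$length / 2 else Inf
  if (!is.finite(half_l)) {
    stop("simulate_tls_scan needs a cylinder with finite length")
  }
  # angular bounding box of the cylinder as seen from the scanner
  ends <- rbind(c0 - half_l * v, c0 + half_l * v)
  corners <- do.call(rbind, lapply(seq_len(2), function(i) {
    # pad each end by the radius in a few cross directions
    B <- cross_section_basis(v)
    do.call(rbind, lapply(seq(0, 2 * pi, length.out = 9)[-9], function(a) {
      ends[i, ] + cyl$radius * (cos(a) * B[1, ] + sin(a) * B[2, ])
    }))
  }))
  w <- sweep(corners, 2, s)
  az <- atan2(w[, 2], w[, 1])
  el <- asin(w[, 3] / sqrt(rowSums(w^2)))
  ctr <- c0 - s
  az0 <- atan2(ctr[2], ctr[1])
  el0 <- asin(ctr[3] / sqrt(sum(ctr^2)))
  # unwrap azimuths around the center direction
  az <- az0 + ((az - az0 + pi) %% (2 * pi) - pi)
  step <- sc$angular_step
  ka <- seq(floor((min(az) - az0) / step) - 1, ceiling((max(az) - az0) / step) + 1)
  ke <- seq(floor((min(el) - el0) / step) - 1, ceiling((max(el) - el0) / step) + 1)
  grid <- expand.grid(az = az0 + ka * step, el = el0 + ke * step)
  dirs <- cbind(cos(grid$el) * cos(grid$az),
                cos(grid$el) * sin(grid$az),
                sin(grid$el))
  hits <- .ray_cylinder(s, dirs, c0, v, cyl$radius)
  keep <- is.finite(hits$t)
  if (!any(keep)) return(NULL)
  pts <- sweep(dirs[keep, , drop = FALSE] * hits$t[keep], 2, s, "+")
  axial <- as.numeric(sweep(pts, 2, c0) %*% v)
  keep2 <- abs(axial) <= half_l + 1e-12
  pts <- pts[keep2, , drop = FALSE]
  if (nrow(pts) == 0L) return(NULL)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             scanner_id = sc$id)
}

# first intersection parameter t of rays s + t*d with the infinite cylinder
.ray_cylinder <- function(s, dirs, c0, v, r) {
  w0 <- s - c0
  # components orthogonal to the axis
  dv <- as.numeric(dirs %*% v)
  wv <- sum(w0 * v)
  d_perp <- dirs - outer(dv, v)
  w_perp <- matrix(w0, nrow(dirs), 3, byrow = TRUE) - outer(rep(wv, nrow(dirs)), v)
  A <- rowSums(d_perp^2)
  Bq <- 2 * rowSums(d_perp * w_perp)
  Cq <- rowSums(w_perp^2) - r^2
  disc <- Bq^2 - 4 * A * Cq
  t <- rep(NA_real_, nrow(dirs))
  ok <- disc >= 0 & A > 1e-15
  t1 <- (-Bq[ok] - sqrt(disc[ok])) / (2 * A[ok])
  t1[t1 <= 0] <- NA_real_
  t[ok] <- t1
  list(t = t)
}
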