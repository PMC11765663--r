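# shared fixtures: the reference study geometry and scanner setups

ref_truth <- function() cylinder_geometry(0.05, 0, pi / 2, c(0, 0, 0), 0.25)

ref_scanner <- function(range = 50, ...) {
  scanner_spec(c(0, range, 0), ...)
}

# near-noiseless scanner: the zero-noise limit of the beam model
quiet_scanner <- function(position = c(0, 50, 0), id = 0L) {
  scanner_spec(position, exit_diameter = 4e-7, divergence_half_angle = 1e-10,
               base_range_sigma = 1e-7, id = id)
}

random_spd2 <- function() {
  A <- matrix(stats::rnorm(4), 2)
  crossprod(A) + 0.05 * diag(2)
}

random_spd3 <- function() {
  A <- matrix(stats::rnorm(9), 3)
  crossprod(A) + 0.05 * diag(3)
}

random_rotation3 <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}
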