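# Shared fixtures: the standard head model, canonical dipole configurations
# (1 mm below the brain surface, |p| = 1e-7 A m), and small numeric helpers.

t1_model <- function(K = 20) four_sphere(skull_divisor = K)

rad_dipole <- function(p = 1e-7) dipole(c(0, 0, 7.8), c(0, 0, p), units = "cm")
tan_dipole <- function(p = 1e-7) dipole(c(0, 0, 7.8), c(0, p, 0), units = "cm")
obl_dipole <- function(p = 1e-7)
  dipole(c(0, 0, 7.8), c(0, p / sqrt(2), p / sqrt(2)), units = "cm")

RZ <- 0.078  # dipole radius shared by the canonical configurations (m)

# max |a - b| normalised by the overall magnitude of b
rel_dev <- function(a, b) max(abs(a - b)) / max(abs(b))

# elementwise relative difference with an underflow floor: values whose true
# magnitude is far below double-precision resolution count as agreeing zeros
rel_each <- function(a, b, floor = 1e-280) abs(a - b) / pmax(abs(a), abs(b), floor)

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_dipole <- function(d, R) {
  dipole(as.numeric(R %*% d$position), as.numeric(R %*% d$moment))
}
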