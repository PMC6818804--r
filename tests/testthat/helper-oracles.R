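# Independent oracles used across the suite.

# Closed-form splitting factor for a symmetric bifurcation
# (lambda2 == lambda3 == lam, equal and opposite half-angles theta):
# alpha = (1 - X sin(theta) sin(phi) / (1 - X cos(theta) sin(gamma))) / 2,
# X = 2 Bo Vt lam^4 / ((Re lam^2 + 16 Vt) Ca).
alpha_symmetric_oracle <- function(Re, Ca, Bo, Vt, theta, phi, gamma, lam) {
  X <- 2 * Bo * Vt * lam^4 / ((Re * lam^2 + 16 * Vt) * Ca)
  a <- 0.5 * (1 - X * sin(theta) * sin(phi) / (1 - X * cos(theta) * sin(gamma)))
  min(1, max(0, a))
}

# Closed-form total wall area of a regular symmetric tree with constant
# per-generation ratios: sum_g 2^g * pi * D0 rd^g * L0 rl^g
symmetric_area_series <- function(n_gen, D0, L0, rd, rl) {
  r <- 2 * rd * rl
  pi * D0 * L0 * sum(r^(0:n_gen))
}

# a small 3-generation (7-airway) asymmetric table for round-trip tests
seven_airway_table <- function() {
  data.frame(id = 0:6,
             parent_id = c(NA, 0L, 0L, 1L, 1L, 2L, 2L),
             diameter = c(0.34, 0.30, 0.21, 0.26, 0.17, 0.18, 0.11),
             length = c(2.5, 0.9, 0.55, 0.8, 0.4, 0.5, 0.3),
             theta = c(0, -0.3, 1.1, -0.25, 0.95, -0.4, 1.0),
             psi = c(0, 0.6, 0.6, -0.8, -0.8, 0.5, 0.5))
}

unit3 <- function(v) v / sqrt(sum(v * v))
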