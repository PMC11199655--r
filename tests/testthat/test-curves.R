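# Characteristic curves of the muscle-tendon model.

test_that("passive force-length curve matches its closed form", {
  # anchors of the exponential curve at s0 and s0 + sM
  expect_equal(passive_force(1.0, 4, 1, 0.6), 0)
  expect_equal(passive_force(1.6, 4, 1, 0.6), 1)
  # interior point: independent arithmetic (e^2 - 1)/(e^4 - 1)
  expect_equal(passive_force(1.3, 4, 1, 0.6),
               (exp(2) - 1) / (exp(4) - 1), tolerance = 1e-14)
  # the anchors hold for any admissible parameter set
  for (p in list(c(3, 0.9, 0.5), c(5, 1.2, 0.7), c(4.2, 1.05, 0.44))) {
    expect_equal(passive_force(p[2], p[1], p[2], p[3]), 0)
    expect_equal(passive_force(p[2] + p[3], p[1], p[2], p[3]), 1)
  }
  # strictly increasing in length; negative below s0 unless clamped. The
  # shape factor sharpens the curve about its pinned anchors: a larger kPE
  # lowers the force between s0 and s0 + sM and raises it beyond s0 + sM.
  l <- seq(0.6, 1.8, by = 0.01)
  expect_true(all(diff(passive_force(l)) > 0))
  expect_lt(passive_force(1.3, 5), passive_force(1.3, 3))
  expect_gt(passive_force(1.75, 5), passive_force(1.75, 3))
  expect_lt(passive_force(0.8), 0)
  expect_identical(passive_force(0.8, clamp = TRUE), 0)
  expect_error(passive_force(NaN), "non-finite")
})

test_that("active force-length curve is normalized, unimodal and smooth", {
  expect_equal(active_force_length(1), 1, tolerance = 1e-12)
  expect_lt(active_force_length(0.5), 1)
  expect_lt(active_force_length(1.6), 1)
  l <- seq(0.4, 1.8, by = 0.005)
  f <- active_force_length(l)
  expect_true(all(f > 0))
  # unimodal: increasing then decreasing around the single optimum
  peak <- which.max(f)
  expect_true(all(diff(f[1:peak]) > 0))
  expect_true(all(diff(f[peak:length(f)]) < 0))
  # frozen value of the adopted coefficient set at the shallow ascending limb
  b <- matrix(c(0.814483478343008, 1.055033428970575, 0.162384573599574,
                0.063303448465465, 0.433004984392647, 0.71677541339776,
                -0.029947116970696, 0.200356847296188, 0.1, 1,
                0.353553390593274, 0), nrow = 3, byrow = TRUE)
  gauss_sum <- function(x) {
    sum(b[, 1] * exp(-0.5 * ((x - b[, 2]) / (b[, 3] + b[, 4] * x))^2))
  }
  expect_equal(active_force_length(0.8), gauss_sum(0.8) / gauss_sum(1),
               tolerance = 1e-12)
})

test_that("force-velocity curve is monotone with an exact inverse", {
  expect_equal(force_velocity(0), 1, tolerance = 1e-12)
  expect_lt(force_velocity(-1), 0.02) # essentially no force at max shortening
  v <- seq(-1.2, 1.2, by = 0.01)
  expect_true(all(diff(force_velocity(v)) > 0))
  for (vv in c(-0.8, -0.3, 0, 0.3, 0.9)) {
    expect_equal(inverse_force_velocity(force_velocity(vv)), vv,
                 tolerance = 1e-10)
  }
  expect_error(inverse_force_velocity(NA_real_), "non-finite")
})

test_that("tendon curve is zero at slack length for any stiffness", {
  for (kt in c(10, 15, 20, 35)) expect_equal(tendon_force(1, kt), 0)
  l <- seq(0.98, 1.08, by = 0.001)
  expect_true(all(diff(tendon_force(l, 35)) > 0))
  # stiffer tendon carries more force at the same strain
  expect_gt(tendon_force(1.03, 35), tendon_force(1.03, 15))
  # strain at unit force multiplier, by bisection on the implemented curve;
  # it must shrink as stiffness grows
  strain_at_one <- function(kt) {
    lo <- 1; hi <- 1.5
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (tendon_force(mid, kt) < 1) lo <- mid else hi <- mid
    }
    (lo + hi) / 2 - 1
  }
  s35 <- strain_at_one(35)
  s15 <- strain_at_one(15)
  expect_equal(tendon_force(1 + s35, 35), 1, tolerance = 1e-9)
  expect_lt(s35, s15)
})

test_that("constant-thickness pennation model projects correctly", {
  expect_equal(pennation_cos(1, 0.1, 0), 1)
  expect_equal(pennation_cos(1, 0.1, 0.2), cos(0.2), tolerance = 1e-14)
  # at double the optimal length sin(theta) halves
  expect_equal(pennation_cos(2, 0.1, pi / 6), cos(asin(0.25)),
               tolerance = 1e-12)
  expect_error(pennation_cos(0.2, 0.1, pi / 4), "shorter")
})

test_that("equilibrium residual vanishes at equilibrium and is linear in fT", {
  mus <- one_muscle()
  st0 <- list(a = 0, lm_tilde = 1, vm_tilde = 0, lt_tilde = 1)
  expect_equal(equilibrium_residual(st0, mus), 0)
  # mismatching the tendon force multiplier by +0.1 shifts the residual by
  # -0.1 F0
  lt1 <- 1
  for (i in 1:60) { # find lt_tilde with fT = 0.1
    if (tendon_force(lt1 + 2^-i, mus$kT) < 0.1) lt1 <- lt1 + 2^-i
  }
  st1 <- list(a = 0, lm_tilde = 1, vm_tilde = 0, lt_tilde = lt1)
  expect_equal(equilibrium_residual(st1, mus), -0.1 * mus$F0,
               tolerance = 1e-6 * mus$F0)
})

test_that("activation dynamics: fixed point, rise, and step response", {
  expect_equal(activation_dynamics_rhs(0.5, 0.5), 0)
  expect_gt(activation_dynamics_rhs(1, 0), 0)
  expect_lt(activation_dynamics_rhs(0, 1), 0)
  # step response oracle: explicit Euler at dt = 1e-5
  a <- 0; t <- 0; dt <- 1e-5
  while (a < 0.95 && t < 1) {
    a <- a + dt * activation_dynamics_rhs(1, a)
    t <- t + dt
  }
  expect_lt(t, 0.1)            # rises within a tenth of a second
  expect_equal(t, 0.08219, tolerance = 0.02) # frozen oracle value
  # at the same activation level, the drive toward full excitation is faster
  # than the decay toward rest (activation time constant < deactivation)
  expect_gt(activation_dynamics_rhs(1, 0.5), -activation_dynamics_rhs(0, 0.5))
  # inversion recovers the driving excitation
  e <- gaittune:::excitation_from_dynamics(
    activation_dynamics_rhs(0.7, 0.3), 0.3)
  expect_equal(e, 0.7, tolerance = 1e-8)
})
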