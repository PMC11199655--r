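# Metabolic energetics: heat terms, non-negativity, aggregation, conversion.

make_fake_fit <- function(a, lm_tilde, vm_tilde, muscles, t = NULL) {
  nt <- nrow(a)
  if (is.null(t)) t <- seq(0, 1, length.out = nt)
  structure(list(
    time = t, pct = 100 * (t - t[1]) / diff(range(t)), muscles = muscles,
    joints = "ankle", a = a, excitation = a, lm_tilde = lm_tilde,
    vm_tilde = vm_tilde, lt_tilde = a * 0 + 1, ft = a * 0,
    e_r = matrix(0, nt, 1), solver = list(mode = "test")
  ), class = "redundancy_fit")
}

test_that("resting muscle consumes nothing; isometric rate matches the heat terms", {
  mus <- one_muscle()
  met <- metabolic_params(body_mass = 75)
  nt <- 5
  zero <- matrix(0, nt, 1)
  # a = 0, v = 0, fiber below the passive region: every term vanishes
  rest <- make_fake_fit(zero, zero + 0.9, zero, mus)
  tr <- muscle_metabolic_rates(rest, met)
  expect_true(all(tr$rate == 0))

  # isometric at a = 1, lm_tilde = 1: activation + maintenance heat only,
  # recomputed term by term as an independent oracle
  iso <- make_fake_fit(zero + 1, zero + 1, zero, mus)
  tr <- muscle_metabolic_rates(iso, met)
  m <- mus$F0 / (60 * 1e4) * mus$lM0 * 1059.7
  u_slow <- sin(pi / 2) * mus$slow_twitch_fraction
  u_fast <- (1 - cos(pi / 2)) * (1 - mus$slow_twitch_fraction)
  oracle <- m * (40 * u_slow + 133 * u_fast) + # activation heat
    m * 1.0 * (74 * u_slow + 111 * u_fast)     # maintenance heat at lm=1
  expect_equal(unname(tr$rate[1, 1]), oracle, tolerance = 1e-12)
})

test_that("adjusted metabolic rate is non-negative even in eccentric phases", {
  mus <- one_muscle()
  met <- metabolic_params(body_mass = 75)
  nt <- 9
  # strong lengthening: negative work dominates the heat terms
  fit <- make_fake_fit(matrix(0.6, nt, 1), matrix(1, nt, 1),
                       matrix(0.8, nt, 1), mus)
  tr <- muscle_metabolic_rates(fit, met)
  expect_true(any(tr$rate_raw < 0)) # the raw Bhargava-style sum goes negative
  expect_true(all(tr$rate >= 0))    # the adjusted rate never does
  expect_true(all(tr$rate[tr$rate_raw < 0] == 0))
})

test_that("leg rate is a pointwise, permutation-invariant sum", {
  x <- matrix(runif(30), 10, 3)
  expect_equal(leg_rate(x), rowSums(x))
  expect_equal(leg_rate(x[, c(3, 1, 2)]), leg_rate(x))
  expect_equal(leg_rate(x[, 1, drop = FALSE]), x[, 1])
})

test_that("whole-body averaging doubles the leg and adds the basal rate", {
  avg <- whole_body_average(rep(127.5, 11), body_mass = 75)
  expect_equal(avg$net_w_kg, 3.4)
  expect_equal(avg$gross_w_kg, 4.6)
  # zero movement costs exactly the basal rate
  expect_equal(whole_body_average(rep(0, 5), 70)$gross_w_kg, 1.2)
  # linearity in the leg rate
  a1 <- whole_body_average(rep(100, 5), 80)
  a2 <- whole_body_average(rep(200, 5), 80)
  expect_equal(a2$net_w_kg, 2 * a1$net_w_kg)
  expect_equal(a2$gross_w_kg - 1.2, 2 * (a1$gross_w_kg - 1.2))
  # gross - net is the basal rate exactly
  expect_equal(a1$gross_w_kg - a1$net_w_kg, 1.2)
})

test_that("gas-exchange conversion is the weighted sum of VO2 and VCO2", {
  expect_equal(brockway_rate(0, 0), 0)
  expect_equal(brockway_rate(0.3, 0.25),
               (16.58 * 0.3 + 4.51 * 0.25) * 1000 / 60, tolerance = 1e-14)
  expect_equal(brockway_rate(0.6, 0.5), 2 * brockway_rate(0.3, 0.25))
})

test_that("on/off timing thresholds at half the maximum", {
  # constant positive trace: on for the whole cycle (>= threshold convention)
  iv <- onoff_timing(rep(0.4, 11))
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start_pct, iv$end_pct), c(0, 100))
  # simple two-point plateau
  iv <- onoff_timing(c(0, 0, 1, 1, 0), pct = c(0, 25, 50, 75, 100))
  expect_equal(c(iv$start_pct, iv$end_pct), c(50, 75))
  # unimodal bump against a brute-force scan
  pct <- seq(0, 100, length.out = 101)
  trace <- exp(-((pct - 40) / 12)^2)
  iv <- onoff_timing(trace, pct)
  on <- trace >= 0.5 * max(trace)
  expect_equal(iv$start_pct, pct[which(on)[1]])
  expect_equal(iv$end_pct, pct[max(which(on))])
  # silence has no on-intervals
  expect_equal(nrow(onoff_timing(rep(0, 5))), 0)
})
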