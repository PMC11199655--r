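# Static fiber-tendon equilibrium and the passive protocol machinery.

test_that("static equilibrium matches a brute-force grid search", {
  mus <- one_muscle(theta0 = 0.2, kt = 25)
  lmt <- 0.315
  eq <- static_equilibrium(mus, lmt, a = 0.4)
  # brute force: residual over a fine grid of normalized tendon lengths
  grid <- seq(0.9, 1.1, by = 1e-6)
  lt <- grid * mus$lTs
  proj <- lmt - lt
  lm <- sqrt(proj^2 + (mus$lM0 * sin(mus$theta0))^2)
  res <- (0.4 * active_force_length(lm / mus$lM0) +
            passive_force(lm / mus$lM0)) * (proj / lm) -
    tendon_force(grid, mus$kT)
  best <- grid[which.min(abs(res))]
  expect_equal(unname(eq$lt_tilde[1, 1]), best, tolerance = 2e-6)
  # geometric closure of the returned state
  lm_back <- eq$lm_tilde * mus$lM0
  expect_equal(mus$lM0 * eq$lm_tilde * eq$cos_theta + mus$lTs * eq$lt_tilde,
               matrix(lmt, 1, 1), tolerance = 1e-9)
})

test_that("passive moment prediction follows the chained arithmetic oracle", {
  # construct the posture whose static equilibrium puts the fiber exactly at
  # 1.3 optimal lengths: find (by in-test bisection on the tendon curve) the
  # tendon length carrying fpas(1.3), then chain F0 * fpas(1.3) * arm
  mus <- muscle_params(data.frame(name = "m", F0 = 1000, lM0 = 0.1,
                                  lTs = 0.2, theta0 = 0, kT = 35))
  target <- passive_force(1.3) # 0.11920...
  lo <- 1; hi <- 1.2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (tendon_force(mid, 35) < target) lo <- mid else hi <- mid
  }
  lmt <- 0.2 * (lo + hi) / 2 + 0.13
  trial <- passive_trial("ankle", angles = c(0, 0.1),
                         q_fixed = c(knee = 0),
                         lmt = matrix(lmt, 2, 1), arm = matrix(0.05, 2, 1))
  pred <- predict_passive_moments(trial, mus)
  oracle <- 1000 * target * 0.05 # 5.9601 N m
  expect_equal(pred$moment[1], oracle, tolerance = 1e-6)
  expect_equal(pred$moment[1], 5.9601, tolerance = 1e-4)
  # the equilibrium in force multipliers is independent of F0, so the moment
  # is exactly linear in F0
  mus2 <- mus; mus2$F0 <- 2000
  pred2 <- predict_passive_moments(trial, mus2)
  expect_equal(pred2$moment[1] / pred$moment[1], 2, tolerance = 1e-9)
  # fiber at its optimal length: zero passive force, zero moment
  trial1 <- passive_trial("ankle", angles = c(0, 0.1),
                          q_fixed = c(knee = 0),
                          lmt = matrix(0.30, 2, 1), arm = matrix(0.05, 2, 1))
  expect_lt(max(abs(predict_passive_moments(trial1, mus)$moment)), 1e-6)
  # below slack the unclamped passive curve yields only a small (slightly
  # compressive) artifact force, bounded by the curve's lower asymptote
  trial0 <- passive_trial("ankle", angles = c(0, 0.1),
                          q_fixed = c(knee = 0),
                          lmt = matrix(0.28, 2, 1), arm = matrix(0.05, 2, 1))
  m0 <- predict_passive_moments(trial0, mus)$moment
  expect_lt(max(abs(m0)), 1) # N m; |fpas| <= 1/(e^4 - 1)
})

test_that("the passive protocol has the eight standard configurations", {
  prot <- build_passive_protocol(toy_geometry(toy6()), n_angles = 7)
  expect_length(prot, 8)
  expect_equal(purrr::map_chr(prot, "joint"),
               c("ankle", "ankle", "ankle", "knee", "knee", "knee",
                 "hip", "hip"))
  deg <- pi / 180
  # ankle sweeps: fixed knee flexion 0, 15, 60
  expect_equal(purrr::map_dbl(prot[1:3], ~ .x$q_fixed[["knee"]]),
               c(0, 15, 60) * deg)
  # third knee sweep: 20 deg dorsiflexion and 15 deg hip extension
  expect_equal(prot[[6]]$q_fixed[["ankle"]], 20 * deg)
  expect_equal(prot[[6]]$q_fixed[["hip"]], -15 * deg)
  # hip sweeps at 15 and 60 deg knee flexion
  expect_equal(purrr::map_dbl(prot[7:8], ~ .x$q_fixed[["knee"]]),
               c(15, 60) * deg)
  # trial tables are congruent
  for (tr in prot) {
    expect_equal(nrow(tr$lmt), length(tr$angles))
    expect_equal(dim(tr$lmt), dim(tr$arm))
  }
})

test_that("slack-length feasibility fix is minimal and idempotent", {
  model <- toy6()
  prot <- make_passive_protocol(model, n_angles = 7)
  # already feasible: unchanged
  fixed <- fix_slack_length(model$muscles, prot, "semimem")
  expect_equal(fixed$lTs, model$muscles$lTs)
  # make the slack length infeasible on purpose
  broken <- model$muscles
  i <- match("semimem", broken$name)
  lmt_min <- min(purrr::map_dbl(prot, ~ min(.x$lmt[, i])))
  broken$lTs[i] <- lmt_min + 0.01
  fixed <- fix_slack_length(broken, prot, "semimem", floor = 0.1)
  expect_lte(fixed$lTs[i],
             lmt_min - 0.1 * broken$lM0[i] * cos(broken$theta0[i]) + 1e-12)
  # idempotent
  again <- fix_slack_length(fixed, prot, "semimem", floor = 0.1)
  expect_equal(again$lTs, fixed$lTs)
  expect_error(fix_slack_length(model$muscles, prot, "nope"), "unknown")
})

test_that("predicted passive moments vary smoothly with posture", {
  model <- toy6()
  prot <- make_passive_protocol(model, n_angles = 61)
  for (tr in prot[c(1, 4, 7)]) {
    m <- predict_passive_moments(tr, model$muscles)$moment
    # second differences shrink with the grid: no kinks from the solver
    d2 <- diff(diff(m))
    expect_lt(max(abs(d2)), 0.1)
  }
  # determinism
  p1 <- predict_passive_moments(prot[[1]], model$muscles)
  p2 <- predict_passive_moments(prot[[1]], model$muscles)
  expect_identical(p1, p2)
})
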