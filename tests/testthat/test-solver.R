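# Muscle-redundancy solver: closed-form oracles, moment balance, diagnostics.

test_that("initial guess is rigid-tendon-consistent and deterministic", {
  model <- toy6()
  g1 <- initial_guess(trial6(), model$muscles, solver_config(mesh = 20))
  g2 <- initial_guess(trial6(), model$muscles, solver_config(mesh = 20))
  expect_identical(g1, g2)
  expect_true(all(g1$lt_tilde == 1))
  # geometric closure at lt_tilde = 1 within 1e-9
  mm <- gaittune:::motion_matrices(resample_motion(trial6(), 21),
                                   model$muscles$name)
  nt <- 21
  closure <- gaittune:::row_mat(model$muscles$lM0, nt) * g1$lm_tilde *
    sqrt(1 - (gaittune:::row_mat(sin(model$muscles$theta0), nt) /
                g1$lm_tilde)^2) +
    gaittune:::row_mat(model$muscles$lTs, nt) * g1$lt_tilde
  expect_equal(closure, mm$lmt, tolerance = 1e-9, ignore_attr = TRUE)
  # infeasible geometry is reported per muscle
  shrunk <- model$muscles
  shrunk$lTs[1] <- 1 # longer than any lMT
  expect_error(initial_guess(trial6(), shrunk, solver_config(mesh = 20)),
               "soleus")
})

test_that("isometric single-muscle activation matches the closed form", {
  mus <- one_muscle()
  for (tau in c(5, 20, 40)) {
    fit <- solve_redundancy(isometric_motion(tau), mus,
                            config = solver_config(mesh = 10,
                                                   rigid_tendon = TRUE))
    expect_equal(max(abs(fit$a - tau / (0.05 * 1000))), 0, tolerance = 1e-3)
  }
})

test_that("a resting problem stays at rest", {
  # zero moments, fiber at its optimal length where the passive force is
  # exactly zero: nothing to do
  mus <- one_muscle()
  fit <- solve_redundancy(isometric_motion(0), mus,
                          config = solver_config(mesh = 10))
  expect_lt(max(fit$a), 1e-3)
  expect_lt(max(abs(fit$e_r)), 1e-3)
})

test_that("two identical muscles share the load symmetrically", {
  mus2 <- muscle_params(data.frame(name = c("m1", "m2"), F0 = 1000,
                                   lM0 = 0.1, lTs = 0.2, theta0 = 0))
  n <- 21
  motion <- tibble::tibble(
    time = seq(0, 1, length.out = n), q_ankle = 0,
    tau_ankle = 30 + 10 * sin(2 * pi * seq(0, 1, length.out = n)),
    lmt_m1 = 0.3, lmt_m2 = 0.3, vmt_m1 = 0, vmt_m2 = 0,
    arm_m1_ankle = 0.05, arm_m2_ankle = 0.05)
  fit <- solve_redundancy(motion, mus2, config = solver_config(mesh = 20))
  expect_lt(max(abs(fit$a[, 1] - fit$a[, 2])), 1e-4)
})

test_that("zero-muscle moments are absorbed exactly by the reserves", {
  # a muscle with zero moment arm cannot contribute: reserves carry tau_ID
  mus <- one_muscle()
  motion <- isometric_motion(3)
  motion$arm_m1_ankle <- 0
  fit <- solve_redundancy(motion, mus, config = solver_config(mesh = 10))
  expect_equal(max(abs(fit$e_r * fit$config$t_reserve - 3)), 0,
               tolerance = 1e-8)
  expect_lt(max(fit$a), 1e-3)
})

test_that("objective equals the sum of its non-negative breakdown terms", {
  fit <- solve_redundancy(trial6(), toy6()$muscles,
                          config = solver_config(mesh = 25))
  expect_true(all(fit$objective$terms >= 0))
  expect_equal(fit$objective$value, sum(fit$objective$terms),
               tolerance = 1e-9)
  # moment balance holds identically at every mesh point
  rep <- residual_report(fit)
  expect_lt(rep$max[rep$metric == "moment_residual_Nm"], 1e-9)
  expect_lt(rep$max[rep$metric == "equilibrium_residual_rel"], 0.02)
})

test_that("mesh refinement leaves the objective stable", {
  # doubling the default mesh changes the objective by less than 1%
  f1 <- solve_redundancy(trial6(), toy6()$muscles,
                         config = solver_config(mesh = 50, periodic = TRUE))
  f2 <- solve_redundancy(trial6(), toy6()$muscles,
                         config = solver_config(mesh = 100, periodic = TRUE))
  expect_equal(f1$objective$value, f2$objective$value, tolerance = 0.01)
})

test_that("tidiers return well-formed tibbles and plots build", {
  fit <- solve_redundancy(trial6(), toy6()$muscles,
                          config = solver_config(mesh = 25))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 101 * 6)
  expect_true(all(c("pct", "muscle", "activation", "lm_tilde") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(fit), "ggplot")
  rs <- tidy_reserves(fit)
  expect_equal(nrow(rs), 101 * 3)
  # metabolic pipeline end to end on the same fit
  met <- metabolic_params(body_mass = 75)
  trace <- muscle_metabolic_rates(fit, met)
  expect_true(all(trace$rate >= 0))
  expect_equal(leg_rate(trace), rowSums(trace$rate))
  expect_s3_class(autoplot(trace), "ggplot")
  expect_s3_class(glance(trace), "tbl_df")
})
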