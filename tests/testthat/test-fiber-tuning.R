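# Fiber-length-informed calibration: normalization rules, stiffness
# conversions, and light tuning invariants (the full recovery study lives in
# the acceptance suite).

test_that("plantarflexor reference normalization is 0.9 x max, scale free", {
  expect_equal(normalize_reference_plantarflexor(c(40, 50, 60)),
               c(0.6, 0.75, 0.9))
  expect_equal(normalize_reference_plantarflexor(rep(3.2, 5)), rep(0.9, 5))
  x <- runif(20, 30, 60)
  expect_equal(normalize_reference_plantarflexor(1000 * x),
               normalize_reference_plantarflexor(x))
  expect_equal(max(normalize_reference_plantarflexor(x)), 0.9)
  expect_error(normalize_reference_plantarflexor(c(1, -1)), "positive")
})

test_that("vasti normalization divides by the reported optimum and propagates", {
  expect_equal(normalize_reference_vasti(c(90, 99), 99),
               c(90 / 99, 1), tolerance = 1e-12)
  expect_equal(normalize_reference_vasti(rep(84, 3), 84), rep(1, 3))
  expect_error(normalize_reference_vasti(1:3, 0), "positive")
  tr <- c(0.9, 1, 1.1)
  prop <- propagate_vasti(tr)
  expect_named(prop, c("vasmed", "vasint"))
  expect_identical(prop$vasmed, tr)
  expect_identical(prop$vasint, tr)
})

test_that("non-normalized stiffness converts units and sums over the subset", {
  mus <- muscle_params(data.frame(name = "m", F0 = 1000, lM0 = 0.05,
                                  lTs = 0.15, kT = 15))
  expect_equal(nonnorm_tendon_stiffness(mus)$stiffness_n_mm, 100)
  three <- muscle_params(data.frame(
    name = c("soleus", "gasmed", "gaslat"), F0 = 1000, lM0 = 0.05,
    lTs = 0.15, kT = 15))
  expect_equal(achilles_aggregate(three), 300)
  # additivity: the aggregate is the sum of the members
  st <- nonnorm_tendon_stiffness(three)
  expect_equal(achilles_aggregate(three), sum(st$stiffness_n_mm))
  # muscles outside the subset do not contribute
  four <- muscle_params(data.frame(
    name = c("soleus", "gasmed", "gaslat", "tibant"), F0 = 1000,
    lM0 = 0.05, lTs = 0.15, kT = 15))
  expect_equal(achilles_aggregate(four), 300)
})

test_that("tuning bounds and spec validation behave", {
  spec <- fiber_tuning_spec()
  expect_equal(spec$kt_bounds, c(10, 35))
  expect_equal(spec$achilles_bounds, c(93, 207))
  expect_equal(spec$untracked_kt, 35)
  expect_error(fiber_tuning_spec(kt_bounds = c(35, 10)))
  # refs for muscles outside the tracked set are rejected
  refs <- tibble::tibble(muscle = "notamuscle", pct = c(0, 100),
                         value = c(1, 1))
  expect_error(
    tune_fiber_params(trial6(), toy6()$muscles, refs),
    "not tracked")
  # refs that do not span the cycle are rejected
  refs2 <- tibble::tibble(muscle = "soleus", pct = c(0, 50), value = c(1, 1))
  expect_error(
    tune_fiber_params(trial6(), toy6()$muscles, refs2,
                      spec = fiber_tuning_spec(tracked = "soleus")),
    "span")
})

test_that("self-referential tuning preserves the tracked fit within its boxes", {
  # References generated by solving the starting model itself: the tracking
  # term starts at zero, so tuning can only trade a little tracked fit for
  # activation economy. The tuned solution must keep the tracked traces
  # close, stay inside every box, and keep the Achilles aggregate in band.
  model <- toy6()
  start <- model$muscles
  start$kT[start$name %in% c("soleus", "gasmed", "gaslat")] <- 15
  cfg <- solver_config(mesh = 25, periodic = TRUE)
  fit0 <- solve_redundancy(trial6(), start, config = cfg)
  pct <- fit0$pct
  refs <- purrr::map_dfr(c("soleus", "gasmed", "gaslat", "vaslat"),
    function(nm) {
      tibble::tibble(muscle = nm, pct = pct,
                     value = fit0$lm_tilde[, match(nm, start$name)])
    })
  tuned <- tune_fiber_params(trial6(), start, refs,
                             config = solver_config(mesh = 25,
                                                    periodic = TRUE,
                                                    maxiter = 100))
  # the tracked traces remain close to the references (the activation term
  # buys a bounded amount of tracked-fit degradation; see the vignette)
  expect_lt(max(tuned$tuned$tracking_rmse), 0.12)
  expect_true(all(tuned$tuned$tracking_rmse <=
                    tuned$tuned$tracking_rmse_baseline + 0.12))
  # every tuned value respects its box
  expect_true(all(tuned$tuned$lM0 >= 0.9 * tuned$tuned$lM0_baseline - 1e-12))
  expect_true(all(tuned$tuned$lM0 <= 1.1 * tuned$tuned$lM0_baseline + 1e-12))
  expect_true(all(tuned$tuned$lTs >= 0.9 * tuned$tuned$lTs_baseline - 1e-12))
  expect_true(all(tuned$tuned$lTs <= 1.1 * tuned$tuned$lTs_baseline + 1e-12))
  expect_true(all(tuned$tuned$kT >= 10 & tuned$tuned$kT <= 35))
  expect_gte(tuned$aggregate_stiffness_n_mm, 93)
  expect_lte(tuned$aggregate_stiffness_n_mm, 207)
  expect_s3_class(tidy(tuned), "tbl_df")
  expect_s3_class(glance(tuned), "tbl_df")
  expect_s3_class(autoplot(tuned), "ggplot")
})
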