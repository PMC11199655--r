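# Shared fixtures, built in code. Heavier fixtures are memoised per session.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

toy6 <- function() fixture("toy6", function() make_toy_model(6, seed = 1))

trial6 <- function() fixture("trial6", function() {
  make_gait_trial(toy6(), seed = 1)
})

# single ideal muscle for closed-form checks
one_muscle <- function(theta0 = 0, kt = 35) {
  muscle_params(data.frame(name = "m1", F0 = 1000, lM0 = 0.1, lTs = 0.2,
                           theta0 = theta0, kT = kt))
}

# isometric single-muscle motion table at optimal fiber length
isometric_motion <- function(tau, n = 11, r = 0.05) {
  tibble::tibble(time = seq(0, 1, length.out = n),
                 q_ankle = 0, tau_ankle = tau,
                 lmt_m1 = 0.3, vmt_m1 = 0, arm_m1_ankle = r)
}
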