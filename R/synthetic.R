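# Seeded synthetic-data generators: a toy planar leg model with known
# ground-truth parameters, gait-like trials whose net joint moments are
# produced by forward evaluation of the muscle model under smooth prescribed
# activations (so the redundancy problem is feasible with near-zero reserves),
# reference normalized fiber-length traces, and passive moment-angle
# protocols. Every generator is a pure function of (model, seed, options).

# Base muscle table of the toy leg. Plantarflexor F0/lTs ratios are sized so
# the aggregate non-normalized Achilles stiffness has literature-like
# magnitude (sum F0/lTs = 9 N/mm per unit kT, i.e. 135 N/mm at kT = 15,
# inside the reported 93-207 N/mm band for healthy adults).
toy_muscle_base <- function() {
  tibble::tribble(
    ~name,     ~F0,  ~lM0,  ~lTs,  ~theta0, ~slow_twitch_fraction, ~group_id,
    "soleus",  1500, 0.050, 0.300, 0.35,    0.80, "plantarflexors",
    "gasmed",   900, 0.060, 0.360, 0.25,    0.55, "plantarflexors",
    "gaslat",   540, 0.065, 0.360, 0.14,    0.50, "plantarflexors",
    "tibant",   700, 0.070, 0.220, 0.10,    0.70, "dorsiflexors",
    "vaslat",  2500, 0.090, 0.160, 0.08,    0.50, "vasti",
    "semimem", 1300, 0.080, 0.340, 0.26,    0.50, "hamstrings",
    "psoas",   1200, 0.100, 0.100, 0.15,    0.50, "hip_flexors",
    "glmax",   2200, 0.140, 0.120, 0.20,    0.55, "glutei"
  )
}

# Constant moment arms (m) about (ankle, knee, hip); the sign convention is
# tau = arm * tendon force with ankle dorsiflexion, knee flexion and hip
# flexion positive, and lMT(q) = lMT_ref - sum_j arm_j q_j.
toy_arm_base <- function() {
  arm <- rbind(
    soleus  = c(-0.048,  0.000,  0.000),
    gasmed  = c(-0.045,  0.018,  0.000),
    gaslat  = c(-0.044,  0.016,  0.000),
    tibant  = c( 0.040,  0.000,  0.000),
    vaslat  = c( 0.000, -0.030,  0.000),
    semimem = c( 0.000,  0.035, -0.055),
    psoas   = c( 0.000,  0.000,  0.045),
    glmax   = c( 0.000,  0.000, -0.060)
  )
  colnames(arm) <- c("ankle", "knee", "hip")
  arm
}

#' Build the toy planar leg model
#'
#' A small sagittal leg with ankle, knee and hip joints, constant moment arms
#' and linear muscle-tendon length geometry
#' \eqn{l_{MT}(q) = l_{MT}^{ref} - \sum_j r_j q_j}. The reference lengths are
#' chosen so that at the neutral posture every muscle sits exactly at its
#' optimal fiber length with the tendon at slack length. Optimal fiber
#' lengths are jittered by up to +/-3% by the seed; the geometry and the
#' parameter table together are the model's ground truth.
#'
#' @param n_muscles Number of muscles, between 2 and 8; the first
#'   `n_muscles` rows of the base table are used (the default 6 spans all
#'   three joints and contains the three-muscle triceps surae needed for the
#'   aggregate Achilles-stiffness constraint).
#' @param seed Integer seed; the model is deterministic for a fixed seed.
#' @return An object of class `toy_model`: a list with the `muscles`
#'   parameter table, `joints`, the `arm` matrix (muscle x joint, m), the
#'   reference lengths `lmt_ref` (m) and the `seed`.
#' @export
make_toy_model <- function(n_muscles = 6, seed = 1) {
  stopifnot(n_muscles >= 2, n_muscles <= 8)
  base <- toy_muscle_base()[seq_len(n_muscles), ]
  jit <- with_seed(seed, stats::runif(n_muscles, -0.03, 0.03))
  base$lM0 <- base$lM0 * (1 + jit)
  muscles <- muscle_params(base)
  arm <- toy_arm_base()[seq_len(n_muscles), , drop = FALSE]
  joints <- colnames(arm)[colSums(arm != 0) > 0]
  arm <- arm[, joints, drop = FALSE]
  lmt_ref <- muscles$lTs + muscles$lM0 * cos(muscles$theta0)
  names(lmt_ref) <- muscles$name
  structure(list(muscles = muscles, joints = joints, arm = arm,
                 lmt_ref = lmt_ref, seed = seed),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat("<toy_model>", nrow(x$muscles), "muscles,",
      paste(x$joints, collapse = "/"), "joints, seed", x$seed, "\n")
  invisible(x)
}

#' Replace the muscle parameters of a toy model
#'
#' Returns the model with a new parameter table but unchanged skeleton
#' geometry (`arm`, `lmt_ref`), the way a scaled model keeps its paths while
#' its muscle-tendon parameters are retuned.
#'
#' @param model A [make_toy_model()] object.
#' @param muscles A [muscle_params()] table with the same muscle names.
#' @return The modified `toy_model`.
#' @export
set_model_params <- function(model, muscles) {
  muscles <- muscle_params(muscles)
  stopifnot(identical(muscles$name, model$muscles$name))
  model$muscles <- muscles
  model
}

#' Geometry provider of the toy model
#'
#' @param model A [make_toy_model()] object.
#' @return `function(q)` mapping a named posture vector (rad) to
#'   `list(lmt, arm)` as consumed by [build_passive_protocol()].
#' @export
toy_geometry <- function(model) {
  function(q) {
    q <- q[model$joints]
    list(lmt = drop(model$lmt_ref - model$arm %*% q), arm = model$arm)
  }
}

# Smooth periodic joint-angle trajectories (rad) and their time derivatives,
# mildly jittered by the seed; s is the cycle fraction in [0, 1].
gait_kinematics <- function(model, seed, t_cycle) {
  jit <- with_seed(seed + 1000L, stats::runif(12, -1, 1))
  amp <- function(base, k) base * (1 + 0.05 * jit[k])
  coef <- list(
    ankle = list(c0 = 0.02, a = c(amp(0.10, 1), amp(0.06, 2)),
                 ph = c(0 + 0.1 * jit[3], 0.8 + 0.1 * jit[4])),
    knee = list(c0 = 0.35, a = c(amp(0.25, 5), amp(0.10, 6)),
                ph = c(pi / 2 + 0.1 * jit[7], 1.2 + 0.1 * jit[8])),
    hip = list(c0 = 0.15, a = c(amp(0.25, 9), amp(0.05, 10)),
               ph = c(1.9 + 0.1 * jit[11], 0 + 0.1 * jit[12]))
  )
  q_fun <- function(t) {
    s <- t / t_cycle
    sapply(model$joints, function(j) {
      cf <- coef[[j]]
      cf$c0 + cf$a[1] * sin(2 * pi * s + cf$ph[1]) +
        cf$a[2] * sin(4 * pi * s + cf$ph[2])
    })
  }
  qd_fun <- function(t) {
    s <- t / t_cycle
    sapply(model$joints, function(j) {
      cf <- coef[[j]]
      (cf$a[1] * 2 * pi * cos(2 * pi * s + cf$ph[1]) +
         cf$a[2] * 4 * pi * cos(4 * pi * s + cf$ph[2])) / t_cycle
    })
  }
  list(q = q_fun, qd = qd_fun)
}

# Smooth periodic prescribed activations: a low baseline plus one or two
# circular (von Mises shaped) bumps per muscle, jittered by the seed.
# Amplitudes of muscles sharing a joint follow their moment-effectiveness
# ratio (arm x F0), the distribution a minimum-sum-of-squared-activations
# criterion selects, so the generated "experimental" traces are consistent
# with the redundancy criterion the calibration assumes.
gait_activations <- function(model, seed) {
  bumps <- list(
    soleus = list(c(0.55, 0.42, 12)),
    gasmed = list(c(0.31, 0.40, 12)),
    gaslat = list(c(0.18, 0.40, 12)),
    tibant = list(c(0.30, 0.75, 8), c(0.15, 0.02, 20)),
    vaslat = list(c(0.40, 0.12, 14)),
    semimem = list(c(0.35, 0.95, 14)),
    psoas = list(c(0.35, 0.62, 10)),
    glmax = list(c(0.40, 0.05, 12))
  )
  n <- nrow(model$muscles)
  jit <- with_seed(seed + 2000L, stats::runif(2 * n, -1, 1))
  function(s) {
    s <- s %% 1
    out <- sapply(seq_len(n), function(i) {
      nm <- model$muscles$name[i]
      val <- 0.02
      for (b in bumps[[nm]]) {
        ctr <- b[2] + 0.02 * jit[2 * i]
        val <- val + b[1] * (1 + 0.05 * jit[2 * i - 1]) *
          exp(b[3] * (cos(2 * pi * (s - ctr)) - 1))
      }
      val
    })
    matrix(out, ncol = n)
  }
}

# Solve the fiber-velocity that satisfies fiber-tendon equilibrium at the
# current state: a*fl*fv(v) + damping*v = ft/cos(theta) - fpas. The left side
# is strictly increasing in v; damped Newton from v = 0.
solve_fiber_velocity <- function(target, afl, damping) {
  v <- numeric(length(target))
  d <- .fv_coef
  for (i in 1:20) {
    z <- d[2] * v + d[3]
    fv <- (d[1] * log(z + sqrt(z^2 + 1)) + d[4]) / .fv_at_zero
    dfv <- d[1] * d[2] / sqrt(z^2 + 1) / .fv_at_zero
    g <- afl * fv + damping * v - target
    step <- g / (afl * dfv + damping)
    v <- v - pmin(pmax(step, -2), 2)
  }
  v
}

# Forward-integrate the contraction dynamics of every muscle independently
# under prescribed activations and muscle-tendon lengths (RK4, fixed step),
# with warm-up cycles so the output cycle is periodic.
forward_muscle_sim <- function(muscles, lmt_fun, a_fun, t_cycle,
                               n_out = 101, nsub = 6, warmup = 2,
                               damping = 0.1) {
  n <- nrow(muscles)
  h <- muscles$lM0 * sin(muscles$theta0)
  rhs <- function(t, lm) {
    lmproj <- sqrt(pmax(lm^2 - h^2, (0.02 * muscles$lM0)^2))
    cos_t <- lmproj / lm
    ltt <- (lmt_fun(t) - lmproj) / muscles$lTs
    lmt_tilde <- lm / muscles$lM0
    fl <- .fl_raw(lmt_tilde) / .fl_at_one
    fpas <- passive_force(lmt_tilde, muscles$kPE, muscles$s0, muscles$sM)
    target <- tendon_force(ltt, muscles$kT) / cos_t - fpas
    a <- drop(a_fun(t / t_cycle))
    v <- solve_fiber_velocity(target, a * fl, damping)
    v * muscles$vmax * muscles$lM0
  }
  eq0 <- static_equilibrium(muscles, matrix(lmt_fun(0), 1),
                            a = matrix(drop(a_fun(0)), 1))
  lm <- drop(eq0$lm_tilde) * muscles$lM0
  t_out <- seq(0, t_cycle, length.out = n_out)
  dt <- t_cycle / ((n_out - 1) * nsub)
  out <- array(NA_real_, dim = c(n_out, n, 2)) # lm_tilde, lt_tilde
  record <- function(idx, t, lm) {
    lmproj <- sqrt(pmax(lm^2 - h^2, (0.02 * muscles$lM0)^2))
    out[idx, , 1] <<- lm / muscles$lM0
    out[idx, , 2] <<- (lmt_fun(t) - lmproj) / muscles$lTs
  }
  rk4 <- function(t, lm) {
    k1 <- rhs(t, lm)
    k2 <- rhs(t + dt / 2, lm + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, lm + dt / 2 * k2)
    k4 <- rhs(t + dt, lm + dt * k3)
    lm + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n_warm <- warmup * (n_out - 1) * nsub
  for (k in seq_len(n_warm)) {
    lm <- rk4(dt * (k - 1) - warmup * t_cycle, lm)
  }
  for (i in seq_len(n_out - 1)) {
    record(i, t_out[i], lm)
    for (s in seq_len(nsub)) {
      lm <- rk4(t_out[i] + dt * (s - 1), lm)
    }
  }
  record(n_out, t_cycle, lm)
  list(time = t_out, lm_tilde = out[, , 1], lt_tilde = out[, , 2])
}

#' Generate a synthetic gait trial
#'
#' Builds one gait cycle of motion inputs for the toy model: smooth periodic
#' joint angles (two harmonics per joint), muscle-tendon lengths and
#' velocities from the linear geometry, and net joint moments obtained by
#' forward evaluation of the muscle model under smooth prescribed activations
#' with compliant tendons. Because the moments are produced by the muscles
#' themselves, the resulting redundancy problem is feasible with near-zero
#' reserve moments under the model's ground-truth parameters.
#'
#' @param model A [make_toy_model()] object (its parameter table is the
#'   ground truth used to generate the moments).
#' @param seed Integer seed controlling the kinematic and activation jitter.
#' @param t_cycle Cycle duration (s), default 1.1.
#' @param n_out Number of output time points over the cycle (default 101).
#' @return A wide motion tibble (see [validate_motion()]) with attributes
#'   `lm_tilde` (the ground-truth normalized fiber-length traces),
#'   `activations` (the prescribed activations) and `seed`.
#' @export
make_gait_trial <- function(model, seed = 1, t_cycle = 1.1, n_out = 101) {
  kin <- gait_kinematics(model, seed, t_cycle)
  act <- gait_activations(model, seed)
  t <- seq(0, t_cycle, length.out = n_out)
  q <- kin$q(t)
  qd <- kin$qd(t)
  lmt <- matrix(rep(model$lmt_ref, each = n_out), n_out) -
    q %*% t(model$arm)
  vmt <- -qd %*% t(model$arm)
  lmt_fun <- function(tt) drop(model$lmt_ref - model$arm %*% kin$q(tt))
  sim <- forward_muscle_sim(model$muscles, lmt_fun, act, t_cycle,
                            n_out = n_out)
  ftmat <- row_mat(model$muscles$F0, n_out) *
    tendon_force(sim$lt_tilde, row_mat(model$muscles$kT, n_out))
  tau <- ftmat %*% model$arm
  out <- tibble::tibble(time = t)
  for (j in seq_along(model$joints)) {
    out[[paste0("q_", model$joints[j])]] <- q[, j]
    out[[paste0("tau_", model$joints[j])]] <- tau[, j]
  }
  for (m in seq_len(nrow(model$muscles))) {
    nm <- model$muscles$name[m]
    out[[paste0("lmt_", nm)]] <- lmt[, m]
    out[[paste0("vmt_", nm)]] <- vmt[, m]
  }
  for (m in seq_len(nrow(model$muscles))) {
    for (j in seq_along(model$joints)) {
      if (model$arm[m, j] != 0) {
        out[[paste0("arm_", model$muscles$name[m], "_", model$joints[j])]] <-
          model$arm[m, j]
      }
    }
  }
  attr(out, "lm_tilde") <- sim$lm_tilde
  attr(out, "activations") <- act((t / t_cycle))
  attr(out, "seed") <- seed
  out
}

#' Reference normalized fiber-length traces from a synthetic trial
#'
#' Exports ground-truth normalized fiber-length trajectories of selected
#' muscles for a generated trial, on the percent-gait-cycle grid, optionally
#' with additive Gaussian noise. The traces emulate the digitized
#' ultrasound-derived fiber-length data used to calibrate the tracked
#' muscles. By default (`source = "redundancy"`) they are the fiber
#' trajectories of the redundancy problem solved under the model's true
#' parameters on a fine independent mesh, so the reference data are
#' consistent with the minimum-squared-activation criterion that the
#' calibration assumes (the way the in vivo data are assumed consistent with
#' the muscle coordination that produced them); `source = "forward"` exports
#' the raw forward-simulation traces under the generator's prescribed
#' activations instead.
#'
#' @param trial A trial from [make_gait_trial()].
#' @param model The model the trial was generated from (its parameter table
#'   is the ground truth).
#' @param which Names of the tracked muscles (default: the plantarflexors
#'   and vasti present in the model).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   normalized traces (default 0).
#' @param seed Seed for the noise.
#' @param source `"redundancy"` (default) or `"forward"`, see above.
#' @param mesh Mesh intervals of the fine reference solve (default 100).
#' @return A long tibble with columns `muscle`, `pct`, `value`.
#' @export
make_reference_fibers <- function(trial, model,
                                  which = intersect(
                                    c("soleus", "gasmed", "gaslat", "vaslat"),
                                    model$muscles$name),
                                  noise_sd = 0, seed = 1,
                                  source = c("redundancy", "forward"),
                                  mesh = 100) {
  source <- match.arg(source)
  idx <- match(which, model$muscles$name)
  stopifnot(!anyNA(idx))
  if (source == "forward") {
    lm <- attr(trial, "lm_tilde")
    stopifnot(!is.null(lm))
    pct <- 100 * (trial$time - trial$time[1]) / diff(range(trial$time))
  } else {
    ref_fit <- solve_redundancy(trial, model$muscles,
                                config = solver_config(mesh = mesh,
                                                       periodic = TRUE))
    lm <- ref_fit$lm_tilde
    pct <- ref_fit$pct
  }
  out <- purrr::map2_dfr(which, idx, function(nm, i) {
    tibble::tibble(muscle = nm, pct = pct, value = lm[, i])
  })
  if (noise_sd > 0) {
    out$value <- out$value +
      with_seed(seed + 3000L, stats::rnorm(nrow(out), 0, noise_sd))
  }
  out
}

#' Generate a synthetic passive moment-angle protocol
#'
#' Builds the eight-trial passive sweep protocol on the toy model and fills
#' in the measured moments by static passive evaluation under the model's
#' ground-truth parameters, optionally with additive Gaussian noise.
#'
#' @param model A [make_toy_model()] object.
#' @param noise_sd Standard deviation of additive Gaussian noise (N m).
#' @param seed Seed for the noise.
#' @param n_angles Sweep postures per trial (default 15).
#' @return A list of eight [passive_trial()] objects with moments set.
#' @export
make_passive_protocol <- function(model, noise_sd = 0, seed = 1,
                                  n_angles = 15) {
  protocol <- build_passive_protocol(toy_geometry(model),
                                     joints = model$joints,
                                     n_angles = n_angles)
  noise <- with_seed(seed + 4000L,
                     stats::rnorm(length(protocol) * n_angles, 0, noise_sd))
  purrr::imap(protocol, function(tr, i) {
    tr$moment <- predict_passive_moments(tr, model$muscles)$moment
    if (noise_sd > 0) {
      tr$moment <- tr$moment + noise[((i - 1) * n_angles + 1):(i * n_angles)]
    }
    tr
  })
}
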