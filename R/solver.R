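# Prescribed-motion muscle-redundancy solver over a gait cycle.
#
# Transcription: the trajectory of normalized tendon length at the mesh points
# is the free variable of a box-constrained nonlinear least-squares problem
# solved by Levenberg-Marquardt (damped Gauss-Newton). Fiber kinematics follow
# from the musculoskeletal geometry, fiber velocity from finite differences on
# the mesh, activation from inverting the fiber-tendon equilibrium, and the
# reserve excitation from the joint-moment residual, e_R = (tau_ID - tau_M)/T_R,
# so moment balance holds identically and reserves enter the objective through
# their heavy weight. All objective terms are squares (activations, reserves,
# fiber velocities, and in the tuning stage the fiber-length tracking error),
# which is what makes the Gauss-Newton formulation exact. With a rigid tendon
# the activations themselves are the free variables and the problem is linear
# least squares.

#' Objective weights of the redundancy and tuning problems
#'
#' Non-negative weights of the objective terms: squared activations (`wa`),
#' fiber-length tracking (`wf`), squared reserve excitations (`wr`), squared
#' normalized fiber velocities (`wv`), and the passive-parameter
#' regularization of the passive tuning stage (`wp`).
#'
#' @param wa,wf,wr,wv,wp Non-negative scalars; defaults 1, 1, 1000, 0.01, 0.1.
#' @return A named list of weights.
#' @export
objective_weights <- function(wa = 1, wf = 1, wr = 1000, wv = 0.01, wp = 0.1) {
  w <- list(wa = wa, wf = wf, wr = wr, wv = wv, wp = wp)
  stopifnot(all(unlist(w) >= 0))
  w
}

#' Solver configuration
#'
#' @param mesh Number of mesh intervals over the cycle (>= 10); trajectories
#'   are discretized on `mesh + 1` points and integrals evaluated by
#'   trapezoidal quadrature on the same grid.
#' @param tol Nonlinear least-squares convergence tolerance.
#' @param periodic Treat the trial as periodic when differentiating fiber
#'   length (default `FALSE`).
#' @param seed Seed for the (optional) initialization jitter.
#' @param rigid_tendon Solve with a rigid tendon (`lt_tilde = 1`); activations
#'   are then the free variables.
#' @param damping Dimensionless fiber damping coefficient (default 0.1).
#' @param t_reserve Maximum reserve moment T_R (N m) scaling the reserve
#'   excitations, default 1.
#' @param init_activation Mid-range activation level of the initial guess.
#' @param jitter Standard deviation of the seeded initialization jitter.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param pen_activation Weight of the quadratic penalty keeping the
#'   algebraically recovered activations inside `[0, 1]`.
#' @param n_starts Number of additional seeded random initializations used by
#'   the multistart passive tuning stage.
#' @return A named list of solver settings.
#' @export
solver_config <- function(mesh = 50, tol = 1e-10, periodic = FALSE, seed = 1,
                          rigid_tendon = FALSE, damping = 0.1, t_reserve = 1,
                          init_activation = 0.1, jitter = 0, maxiter = 200,
                          pen_activation = 100, n_starts = 5) {
  stopifnot(mesh >= 10, tol > 0, t_reserve > 0)
  list(mesh = mesh, scheme = "trapezoidal", tol = tol, periodic = periodic,
       seed = seed, rigid_tendon = rigid_tendon, damping = damping,
       t_reserve = t_reserve, init_activation = init_activation,
       jitter = jitter, maxiter = maxiter, pen_activation = pen_activation,
       n_starts = n_starts)
}

trap_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

grad_matrix <- function(x, t, periodic = FALSE) {
  n <- nrow(x)
  g <- x * 0
  if (periodic) {
    dt0 <- (t[2] - t[1]) + (t[n] - t[n - 1])
    g[1, ] <- (x[2, ] - x[n - 1, ]) / dt0
    g[n, ] <- g[1, ]
  } else {
    g[1, ] <- (x[2, ] - x[1, ]) / (t[2] - t[1])
    g[n, ] <- (x[n, ] - x[n - 1, ]) / (t[n] - t[n - 1])
  }
  if (n > 2) {
    g[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) /
      (t[3:n] - t[1:(n - 2)])
  }
  g
}

# Broadcast a per-muscle parameter vector to a (time x muscle) matrix.
row_mat <- function(v, nt) matrix(v, nrow = nt, ncol = length(v), byrow = TRUE)

# Fiber geometry under the constant-thickness pennation model, with a smooth
# floor on the projected fiber length so the evaluation stays defined at
# extreme iterates.
fiber_geometry <- function(lmt, lt, lm0m, theta0m) {
  proj <- pmax(lmt - lt, 0.02 * lm0m)
  h <- lm0m * sin(theta0m)
  lm <- sqrt(proj^2 + h^2)
  list(lm_tilde = lm / lm0m, cos_theta = proj / lm, lm = lm)
}

# Evaluate all trajectory quantities from the normalized tendon-force
# trajectories (compliant tendon). Tendon force is the free variable (rather
# than tendon length) so that the heavily weighted moment-balance residuals
# are linear in the decision variables; tendon length follows from the
# closed-form inverse of the tendon curve.
eval_compliant <- function(ftt, mus, mm, config) {
  nt <- length(mm$time)
  lm0m <- row_mat(mus$lM0, nt)
  ltsm <- row_mat(mus$lTs, nt)
  ktm <- row_mat(mus$kT, nt)
  ltt <- tendon_length_from_force(ftt, ktm)
  geo <- fiber_geometry(mm$lmt, ltt * ltsm, lm0m, row_mat(mus$theta0, nt))
  vm <- grad_matrix(geo$lm, mm$time, config$periodic)
  vtilde <- vm / (lm0m * row_mat(mus$vmax, nt))
  fl <- .fl_raw(geo$lm_tilde) / .fl_at_one
  fv <- pmax(.fv_raw(vtilde) / .fv_at_zero, 0.01)
  fpas <- passive_force(geo$lm_tilde, row_mat(mus$kPE, nt),
                        row_mat(mus$s0, nt), row_mat(mus$sM, nt))
  a <- (ftt / geo$cos_theta - fpas - config$damping * vtilde) / (fl * fv)
  FT <- row_mat(mus$F0, nt) * ftt
  tau_m <- moment_sum(mm$arm, FT)
  e_r <- (mm$tau - tau_m) / config$t_reserve
  list(a = a, lm_tilde = geo$lm_tilde, vm_tilde = vtilde, lt_tilde = ltt,
       cos_theta = geo$cos_theta, ft = FT, fm = FT, tau_m = tau_m, e_r = e_r)
}

# Admissible normalized tendon-force range: the tendon-curve inverse needs
# ftt > -c1*exp(kT(1-c2)), which over kT in [10, 35] is tightest at -0.21;
# -0.18 keeps a safe margin for any admissible stiffness.
ftt_bounds <- function(mus, nt) {
  list(lower = rep(-0.18, nt * nrow(mus)), upper = rep(2.5, nt * nrow(mus)))
}

# Evaluate trajectory quantities with a rigid tendon (lt_tilde = 1);
# activations are given directly.
eval_rigid <- function(a, mus, mm, config) {
  nt <- length(mm$time)
  lm0m <- row_mat(mus$lM0, nt)
  ltsm <- row_mat(mus$lTs, nt)
  geo <- fiber_geometry(mm$lmt, ltsm, lm0m, row_mat(mus$theta0, nt))
  vm <- geo$cos_theta * mm$vmt # d lM/dt with constant tendon length
  vtilde <- vm / (lm0m * row_mat(mus$vmax, nt))
  fl <- .fl_raw(geo$lm_tilde) / .fl_at_one
  fv <- pmax(.fv_raw(vtilde) / .fv_at_zero, 0.01)
  fpas <- passive_force(geo$lm_tilde, row_mat(mus$kPE, nt),
                        row_mat(mus$s0, nt), row_mat(mus$sM, nt))
  FT <- row_mat(mus$F0, nt) *
    (a * fl * fv + fpas + config$damping * vtilde) * geo$cos_theta
  tau_m <- moment_sum(mm$arm, FT)
  e_r <- (mm$tau - tau_m) / config$t_reserve
  list(a = a, lm_tilde = geo$lm_tilde, vm_tilde = vtilde,
       lt_tilde = matrix(1, nt, nrow(mus)), cos_theta = geo$cos_theta,
       ft = FT, fm = FT, tau_m = tau_m, e_r = e_r)
}

moment_sum <- function(arm, FT) {
  nj <- dim(arm)[3]
  out <- matrix(0, nrow(FT), nj)
  for (j in seq_len(nj)) out[, j] <- rowSums(arm[, , j, drop = FALSE][, , 1] * FT)
  colnames(out) <- dimnames(arm)[[3]]
  out
}

# Weighted residual vector and per-term sums of squares for a trajectory
# evaluation; `track` is a list(idx, ref) for the fiber tracking term.
traj_residuals <- function(ev, weights, config, wt, track = NULL) {
  sw <- sqrt(wt)
  r_a <- sqrt(weights$wa) * sw * ev$a
  r_r <- sqrt(weights$wr) * sw * ev$e_r
  r_v <- sqrt(weights$wv) * sw * ev$vm_tilde
  viol <- pmin(ev$a, 0) + pmax(ev$a - 1, 0)
  r_p <- sqrt(config$pen_activation) * sw * viol
  r_f <- NULL
  if (!is.null(track)) {
    r_f <- sqrt(weights$wf) * sw * (ev$lm_tilde[, track$idx, drop = FALSE] - track$ref)
  }
  list(
    resid = c(r_a, r_r, r_v, r_p, r_f),
    terms = c(activation = sum(r_a^2), reserve = sum(r_r^2),
              velocity = sum(r_v^2), activation_penalty = sum(r_p^2),
              tracking = if (is.null(r_f)) 0 else sum(r_f^2))
  )
}

# Sparse forward-difference Jacobian for the trajectory least-squares
# problems. A tendon-length variable x[t, n] only touches residual rows at
# times t-1, t, t+1 (the fiber-velocity stencil), so interior mesh columns
# are perturbed three-at-a-time (t mod 3 coloring) and the differences
# attributed to disjoint row blocks; boundary mesh columns (which wrap under
# periodic differencing) and the appended parameter columns are finite-
# differenced individually with full columns. This reduces a Jacobian from
# one evaluation per column to about eight per muscle.
make_sparse_jac <- function(fn, nt, nm, nj, tracked_idx = integer(0),
                            n_param = 0, n_tail = 0) {
  nl <- length(tracked_idx)
  off_a <- 0L
  off_r <- nt * nm
  off_v <- off_r + nt * nj
  off_p <- off_v + nt * nm
  off_f <- off_p + nt * nm
  n_rows <- off_f + nt * nl + n_tail
  rows_for <- function(tt, n) {
    l <- match(n, tracked_idx)
    c(off_a + (n - 1) * nt + tt,
      off_r + rep((seq_len(nj) - 1) * nt, each = length(tt)) + tt,
      off_v + (n - 1) * nt + tt,
      off_p + (n - 1) * nt + tt,
      if (!is.na(l)) off_f + (l - 1) * nt + tt)
  }
  boundary <- unique(pmin(pmax(c(1, 2, nt - 2, nt - 1, nt), 1), nt))
  interior <- setdiff(seq_len(nt), boundary)
  phases <- split(interior, interior %% 3)
  function(par, ...) {
    r0 <- fn(par)
    stopifnot(length(r0) == n_rows)
    jac <- matrix(0, n_rows, length(par))
    h <- 1e-6
    cdiff <- function(cols, hh) (fn(`[<-`(par, cols, par[cols] + hh)) -
                                   fn(`[<-`(par, cols, par[cols] - hh))) / (2 * hh)
    for (n in seq_len(nm)) {
      base_col <- (n - 1) * nt
      for (ts in phases) {
        dr <- cdiff(base_col + ts, h)
        for (t in ts) {
          rows <- rows_for(max(1, t - 1):min(nt, t + 1), n)
          jac[rows, base_col + t] <- dr[rows]
        }
      }
      for (t in boundary) {
        jac[, base_col + t] <- cdiff(base_col + t, h)
      }
    }
    for (k in seq_len(n_param)) {
      col <- nt * nm + k
      jac[, col] <- cdiff(col, 1e-6 * max(1, abs(par[col])))
    }
    jac
  }
}

# Projected Levenberg-Marquardt for small box-constrained least-squares
# problems whose residual function itself contains an nls.lm solve (the
# bilevel tuning stages): minpack.lm's C core is not re-entrant, so the outer
# descent is run in R. Forward-difference Jacobian (differencing inward at
# active bounds), Marquardt damping on the scaled normal equations, steps
# projected onto the box.
projected_lm <- function(fn, par, lower, upper, maxiter = 25, h = 1e-4,
                         ftol = 1e-8, ptol = 1e-6) {
  clip <- function(x) pmin(pmax(x, lower), upper)
  par <- clip(par)
  r <- fn(par)
  obj <- sum(r^2)
  lambda <- 1e-3
  niter <- 0L
  converged <- FALSE
  message <- "maximum iterations reached"
  for (it in seq_len(maxiter)) {
    niter <- it
    jac <- vapply(seq_along(par), function(k) {
      hk <- if (par[k] + h <= upper[k]) h else -h
      (fn(`[<-`(par, k, par[k] + hk)) - r) / hk
    }, numeric(length(r)))
    a <- crossprod(jac)
    g <- crossprod(jac, r)
    improved <- FALSE
    for (try in 1:12) {
      damp <- diag(diag(a) + 1e-12, nrow(a))
      step <- tryCatch(drop(solve(a + lambda * damp, -g)),
                       error = function(e) NULL)
      if (is.null(step)) {
        lambda <- lambda * 10
        next
      }
      par_new <- clip(par + step)
      r_new <- fn(par_new)
      obj_new <- sum(r_new^2)
      if (obj_new < obj) {
        delta <- max(abs(par_new - par))
        rel <- (obj - obj_new) / (obj + 1e-300)
        par <- par_new
        r <- r_new
        obj <- obj_new
        lambda <- max(lambda / 3, 1e-10)
        improved <- TRUE
        if (rel < ftol || delta < ptol) {
          converged <- TRUE
          message <- "relative objective/step change below tolerance"
        }
        break
      }
      lambda <- lambda * 5
    }
    if (!improved) {
      converged <- TRUE
      message <- "no descent direction found (local minimum)"
      break
    }
    if (converged) break
  }
  list(par = par, objective = obj, niter = niter, converged = converged,
       message = message)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Initial guess for the redundancy solver
#'
#' Rigid-tendon-consistent initialization: normalized tendon length 1
#' everywhere, fiber length from the musculoskeletal geometry, and mid-range
#' activations (optionally jittered; deterministic for a fixed seed).
#'
#' @inheritParams solve_redundancy
#' @return A list with matrices `a`, `lm_tilde` and `lt_tilde` on the mesh.
#' @export
initial_guess <- function(motion, muscles, config = solver_config()) {
  muscles <- muscle_params(muscles)
  mm <- motion_matrices(resample_motion(motion, config$mesh + 1), muscles$name)
  nt <- length(mm$time)
  ltsm <- row_mat(muscles$lTs, nt)
  proj <- mm$lmt - ltsm
  if (any(proj <= 0)) {
    bad <- unique(muscles$name[which(proj <= 0, arr.ind = TRUE)[, 2]])
    stop("geometry infeasible (lMT < lTs) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  geo <- fiber_geometry(mm$lmt, ltsm, row_mat(muscles$lM0, nt),
                        row_mat(muscles$theta0, nt))
  a <- matrix(config$init_activation, nt, nrow(muscles))
  if (config$jitter > 0) {
    a <- a + with_seed(config$seed,
                       matrix(stats::rnorm(length(a), 0, config$jitter), nt))
    a <- pmin(pmax(a, 0), 1)
  }
  list(a = a, lm_tilde = geo$lm_tilde,
       lt_tilde = matrix(1, nt, nrow(muscles)))
}

lm_control <- function(config) {
  minpack.lm::nls.lm.control(maxiter = config$maxiter, ftol = config$tol,
                             ptol = config$tol, gtol = 0, maxfev = 100000L,
                             nprint = 0)
}

# Rigid-tendon least-squares stage: activations are the free variables.
solve_rigid_stage <- function(a0, mus, mm, weights, config, track = NULL) {
  nt <- length(mm$time)
  wt <- trap_weights(mm$time)
  fn <- function(par) {
    a <- matrix(par, nt)
    traj_residuals(eval_rigid(a, mus, mm, config), weights, config, wt,
                   track)$resid
  }
  out <- minpack.lm::nls.lm(par = as.vector(a0), fn = fn,
                            lower = rep(0, length(a0)),
                            upper = rep(1, length(a0)),
                            control = lm_control(config))
  matrix(out$par, nt)
}

#' Solve the muscle-redundancy problem for a prescribed motion
#'
#' Distributes the prescribed net joint moments over the muscles of the model
#' by minimizing the weighted integral of squared activations, squared reserve
#' excitations and squared normalized fiber velocities, subject to
#' fiber-tendon equilibrium at every muscle and moment balance (with reserve
#' actuators) at every joint, over one gait cycle. See the package vignette
#' for the transcription.
#'
#' @param motion A wide motion table (see [validate_motion()]).
#' @param muscles A [muscle_params()] table.
#' @param weights [objective_weights()].
#' @param config [solver_config()].
#' @return An object of class `redundancy_fit` with trajectory matrices
#'   (`a`, `lm_tilde`, `vm_tilde`, `lt_tilde`, `ft`, `e_r`, ...), the
#'   objective value and its per-term breakdown, and solver diagnostics.
#'   Use [tidy()] for a long tibble of trajectories and [glance()] for a
#'   one-row summary.
#' @export
solve_redundancy <- function(motion, muscles, weights = objective_weights(),
                             config = solver_config()) {
  muscles <- muscle_params(muscles)
  mm <- motion_matrices(resample_motion(motion, config$mesh + 1), muscles$name)
  guess <- initial_guess(motion, muscles, config)
  wt <- trap_weights(mm$time)
  a_rigid <- solve_rigid_stage(guess$a, muscles, mm, weights, config)

  if (config$rigid_tendon) {
    ev <- eval_rigid(a_rigid, muscles, mm, config)
    info <- list(mode = "rigid", converged = TRUE, message = "linear stage",
                 niter = NA_integer_)
  } else {
    nt <- length(mm$time)
    ev_rigid <- eval_rigid(a_rigid, muscles, mm, config)
    b <- ftt_bounds(muscles, nt)
    ftt0 <- pmin(pmax(ev_rigid$ft / row_mat(muscles$F0, nt), b$lower + 0.01),
                 b$upper - 0.01)
    fn <- function(par) {
      ftt <- matrix(par, nt)
      traj_residuals(eval_compliant(ftt, muscles, mm, config), weights,
                     config, wt)$resid
    }
    jac <- make_sparse_jac(fn, nt, nrow(muscles), length(mm$joints))
    out <- minpack.lm::nls.lm(par = as.vector(ftt0), fn = fn, jac = jac,
                              lower = b$lower, upper = b$upper,
                              control = lm_control(config))
    ev <- eval_compliant(matrix(out$par, nt), muscles, mm, config)
    info <- list(mode = "compliant", converged = out$info %in% 1:4,
                 message = out$message, niter = out$niter)
  }
  build_fit(ev, muscles, mm, weights, config, info)
}

build_fit <- function(ev, muscles, mm, weights, config, info, track = NULL) {
  wt <- trap_weights(mm$time)
  res <- traj_residuals(ev, weights, config, wt, track)
  dadt <- grad_matrix(ev$a, mm$time, config$periodic)
  a_cl <- pmin(pmax(ev$a, 0), 1)
  exc <- matrix(excitation_from_dynamics(as.vector(dadt), as.vector(a_cl)),
                nrow(a_cl))
  dimnames(ev$a) <- list(NULL, muscles$name)
  structure(list(
    time = mm$time,
    pct = 100 * (mm$time - mm$time[1]) / diff(range(mm$time)),
    muscles = muscles,
    joints = mm$joints,
    a = a_cl,
    excitation = exc,
    lm_tilde = ev$lm_tilde,
    vm_tilde = ev$vm_tilde,
    lt_tilde = ev$lt_tilde,
    cos_theta = ev$cos_theta,
    ft = ev$ft,
    fm = ev$fm,
    e_r = ev$e_r,
    tau_m = ev$tau_m,
    tau_id = mm$tau,
    objective = list(value = sum(res$terms), terms = res$terms),
    diagnostics = list(
      max_activation_violation = max(abs(ev$a - a_cl)),
      max_reserve_moment = max(abs(ev$e_r)) * config$t_reserve,
      max_reserve_excitation = max(abs(ev$e_r))
    ),
    weights = weights,
    config = config,
    solver = info
  ), class = "redundancy_fit")
}

#' @export
print.redundancy_fit <- function(x, ...) {
  cat("<redundancy_fit> ", x$solver$mode, "-tendon, ",
      length(x$time), " mesh points, ", nrow(x$muscles), " muscles, ",
      length(x$joints), " joints\n", sep = "")
  cat("  objective: ", format(x$objective$value, digits = 6),
      "  max |reserve moment|: ",
      format(x$diagnostics$max_reserve_moment, digits = 3), " N m\n", sep = "")
  invisible(x)
}

#' Residual diagnostics of a solved trial
#'
#' Recomputes, by forward evaluation of the stored trajectories, the
#' moment-balance residual at every joint (inverse-dynamics moment minus
#' muscle moment minus reserve moment) and the fiber-tendon equilibrium
#' residual of every muscle, normalized by its maximum isometric force.
#' For a rigid-tendon solution the tendon-curve equilibrium does not apply
#' and the equilibrium residual is reported as zero by construction.
#'
#' @param fit A `redundancy_fit`.
#' @return A tibble with columns `metric`, `max`, `mean`.
#' @export
residual_report <- function(fit) {
  mom <- abs(fit$tau_id - fit$tau_m - fit$e_r * fit$config$t_reserve)
  eq <- if (fit$solver$mode == "rigid") {
    matrix(0, length(fit$time), nrow(fit$muscles))
  } else {
    nt <- length(fit$time)
    fl <- .fl_raw(fit$lm_tilde) / .fl_at_one
    fv <- pmax(.fv_raw(fit$vm_tilde) / .fv_at_zero, 0.01)
    fpas <- passive_force(fit$lm_tilde, row_mat(fit$muscles$kPE, nt),
                          row_mat(fit$muscles$s0, nt),
                          row_mat(fit$muscles$sM, nt))
    fib <- (fit$a * fl * fv + fpas +
              fit$config$damping * fit$vm_tilde) * fit$cos_theta
    abs(fib - tendon_force(fit$lt_tilde, row_mat(fit$muscles$kT, nt)))
  }
  tibble::tibble(
    metric = c("moment_residual_Nm", "equilibrium_residual_rel"),
    max = c(max(mom), max(eq)),
    mean = c(mean(mom), mean(eq))
  )
}
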