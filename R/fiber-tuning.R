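# Stage-1 calibration: tune optimal fiber length, tendon slack length and
# normalized tendon stiffness of the tracked muscles so the simulated
# normalized fiber lengths match reference traces, while the full redundancy
# problem is solved for all muscles. The trajectory variables and the tuned
# parameters are optimized jointly in one box-constrained nonlinear
# least-squares problem.

#' Normalize a plantarflexor reference fiber-length trace
#'
#' Reference plantarflexor traces are reported without optimal fiber lengths;
#' they are normalized to their maximum value and multiplied by 0.9, which
#' places the muscle on the shallow ascending limb of the force-length curve.
#' The rule is scale invariant, so traces in millimetres, metres or already
#' normalized units are all acceptable.
#'
#' @param raw_trace Positive fiber-length trace (any consistent unit).
#' @return Normalized trace with maximum exactly 0.9.
#' @export
normalize_reference_plantarflexor <- function(raw_trace) {
  if (any(!is.finite(raw_trace)) || any(raw_trace <= 0)) {
    stop("reference trace must be positive and finite", call. = FALSE)
  }
  0.9 * raw_trace / max(raw_trace)
}

#' Normalize a vasti reference fiber-length trace
#'
#' Vastus lateralis traces are normalized by the optimal fiber length
#' reported with them; `propagate_vasti()` copies the resulting trace to the
#' vastus medialis and intermedius, which are assumed to operate in the same
#' region of the force-length curve.
#'
#' @param raw_trace Fiber-length trace (same unit as `lm0_reported`).
#' @param lm0_reported Reported optimal fiber length (> 0).
#' @return `normalize_reference_vasti()`: the normalized trace.
#' @export
normalize_reference_vasti <- function(raw_trace, lm0_reported) {
  if (!is.finite(lm0_reported) || lm0_reported <= 0) {
    stop("reported optimal fiber length must be positive", call. = FALSE)
  }
  raw_trace / lm0_reported
}

#' @rdname normalize_reference_vasti
#' @param trace A normalized trace (e.g. of the vastus lateralis).
#' @param names Muscles to propagate the trace to.
#' @return `propagate_vasti()`: a named list of identical traces.
#' @export
propagate_vasti <- function(trace, names = c("vasmed", "vasint")) {
  stats::setNames(rep(list(trace), length(names)), names)
}

#' Non-normalized tendon stiffness
#'
#' Converts the dimensionless tendon stiffness to the linearized
#' non-normalized stiffness \eqn{k_T F^0 / l_T^s}, reported in N/mm.
#' `achilles_aggregate()` sums it over the triceps surae (soleus and both
#' gastrocnemii), the quantity constrained to the experimentally reported
#' 93-207 N/mm band during tuning.
#'
#' @param muscles A [muscle_params()] table.
#' @return `nonnorm_tendon_stiffness()`: a tibble with columns `name` and
#'   `stiffness_n_mm`.
#' @examples
#' m <- muscle_params(data.frame(name = "m", F0 = 1000, lM0 = 0.05,
#'                               lTs = 0.15, kT = 15))
#' nonnorm_tendon_stiffness(m) # 100 N/mm
#' @export
nonnorm_tendon_stiffness <- function(muscles) {
  muscles <- muscle_params(muscles)
  tibble::tibble(name = muscles$name,
                 stiffness_n_mm = muscles$kT * muscles$F0 / muscles$lTs / 1000)
}

#' @rdname nonnorm_tendon_stiffness
#' @param subset Names of the triceps surae muscles.
#' @return `achilles_aggregate()`: the summed stiffness (N/mm).
#' @export
achilles_aggregate <- function(muscles,
                               subset = c("soleus", "gasmed", "gaslat")) {
  st <- nonnorm_tendon_stiffness(muscles)
  sum(st$stiffness_n_mm[st$name %in% subset])
}

#' Specification of the fiber-tuning stage
#'
#' @param tracked Names of the tracked muscles whose parameters are tuned
#'   (default: the triceps surae and vasti muscle names of the full-leg
#'   models; intersected with the model at run time).
#' @param lm0_frac,lts_frac Half-width of the bounds on optimal fiber length
#'   and tendon slack length, as a fraction of the linearly scaled baseline
#'   (default 0.1, i.e. +/-10%).
#' @param kt_bounds Bounds of the normalized tendon stiffness, default
#'   `c(10, 35)`.
#' @param untracked_kt Normalized stiffness fixed for all untracked muscles
#'   (default 35).
#' @param achilles Names of the plantarflexor subset whose aggregate
#'   non-normalized stiffness is constrained.
#' @param achilles_bounds Bounds on the aggregate stiffness (N/mm), default
#'   `c(93, 207)`.
#' @param w_agg Weight of the penalty enforcing the aggregate-stiffness box
#'   during the least-squares iterations (the final parameters are projected
#'   exactly into the box).
#' @return A named list.
#' @export
fiber_tuning_spec <- function(tracked = c("soleus", "gasmed", "gaslat",
                                          "vaslat", "vasmed", "vasint"),
                              lm0_frac = 0.1, lts_frac = 0.1,
                              kt_bounds = c(10, 35), untracked_kt = 35,
                              achilles = c("soleus", "gasmed", "gaslat"),
                              achilles_bounds = c(93, 207), w_agg = 10) {
  stopifnot(kt_bounds[1] < kt_bounds[2],
            achilles_bounds[1] < achilles_bounds[2])
  list(tracked = tracked, lm0_frac = lm0_frac, lts_frac = lts_frac,
       kt_bounds = kt_bounds, untracked_kt = untracked_kt,
       achilles = achilles, achilles_bounds = achilles_bounds, w_agg = w_agg)
}

# Interpolate long reference traces (muscle, pct, value) onto the mesh.
refs_on_mesh <- function(refs, tracked, pct) {
  sapply(tracked, function(nm) {
    tr <- refs[refs$muscle == nm, ]
    if (!nrow(tr)) stop("no reference trace for ", nm, call. = FALSE)
    if (max(tr$pct) < max(pct) - 1e-6 || min(tr$pct) > min(pct) + 1e-6) {
      stop("reference trace for ", nm, " does not span the gait cycle",
           call. = FALSE)
    }
    stats::approx(tr$pct, tr$value, xout = pct)$y
  })
}

#' Tune fiber and tendon parameters against reference fiber-length traces
#'
#' Jointly optimizes the state trajectories of all muscles and the optimal
#' fiber length, tendon slack length and normalized tendon stiffness of the
#' tracked muscles, minimizing the weighted integral of squared activations,
#' fiber-length tracking error against the reference traces, squared reserve
#' excitations and squared fiber velocities, subject to the muscle dynamics,
#' moment balance, the +/-10% parameter boxes around the linearly scaled
#' baseline, the tendon-stiffness box, and the aggregate Achilles
#' non-normalized stiffness band. Untracked muscles keep their stiffness
#' fixed. The baseline values in `muscles` define the bounds.
#'
#' @param motion A wide motion table of one gait cycle.
#' @param muscles Linearly scaled baseline [muscle_params()] table.
#' @param refs Reference traces: a long tibble with columns `muscle`, `pct`
#'   (percent gait cycle) and `value` (normalized fiber length), covering
#'   the tracked muscles.
#' @param spec [fiber_tuning_spec()].
#' @param weights [objective_weights()].
#' @param config [solver_config()].
#' @return An object of class `fiber_tuning_fit`: tuned parameter table
#'   (`params`), a per-muscle summary (`tuned`), the final redundancy
#'   solution (`solution`), the aggregate Achilles stiffness and whether its
#'   constraint is active, and solver diagnostics. [tidy()] returns the
#'   per-muscle parameter summary, [glance()] a one-row fit summary.
#' @export
tune_fiber_params <- function(motion, muscles, refs,
                              spec = fiber_tuning_spec(),
                              weights = objective_weights(),
                              config = solver_config()) {
  muscles <- muscle_params(muscles)
  tracked <- intersect(spec$tracked, muscles$name)
  if (!length(tracked)) stop("no tracked muscles present in the model",
                             call. = FALSE)
  extra <- setdiff(unique(refs$muscle), tracked)
  if (length(extra)) {
    stop("reference traces for muscles that are not tracked: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  base <- muscles
  base$kT[!base$name %in% tracked] <- spec$untracked_kt
  mm <- motion_matrices(resample_motion(motion, config$mesh + 1), base$name)
  pct <- 100 * (mm$time - mm$time[1]) / diff(range(mm$time))
  ref_mat <- refs_on_mesh(refs, tracked, pct)
  idx <- match(tracked, base$name)
  ach_idx <- match(intersect(spec$achilles, tracked), base$name)
  nt <- length(mm$time)
  wt <- trap_weights(mm$time)
  npar_traj <- nt * nrow(base)

  agg_resid <- function(mus) {
    agg <- achilles_aggregate(mus, spec$achilles)
    sqrt(spec$w_agg) * (pmax(agg - spec$achilles_bounds[2], 0) +
                          pmax(spec$achilles_bounds[1] - agg, 0))
  }

  # Feasible initialization of the tracked stiffnesses: when the baseline
  # aggregate Achilles stiffness lies outside its band, scale the tracked kT
  # toward the band midpoint (clipped to the kT box) so the optimization
  # starts from a feasible aggregate rather than against the penalty.
  start <- base
  agg0 <- achilles_aggregate(start, spec$achilles)
  if (length(ach_idx) &&
      (agg0 < spec$achilles_bounds[1] || agg0 > spec$achilles_bounds[2])) {
    target <- mean(spec$achilles_bounds)
    start$kT[ach_idx] <- pmin(pmax(start$kT[ach_idx] * target / agg0,
                                   spec$kt_bounds[1]), spec$kt_bounds[2])
  }
  # tracked muscles outside the Achilles subset start at the middle of the
  # stiffness box rather than at a bound
  other <- setdiff(idx, ach_idx)
  start$kT[other] <- mean(spec$kt_bounds)
  start$kT[idx] <- pmin(pmax(start$kT[idx], spec$kt_bounds[1]),
                        spec$kt_bounds[2])

  # warm start: solve the redundancy problem at the starting parameters
  base_fit <- solve_redundancy(motion, start, weights, config)
  np <- length(idx)

  # The tracking error is nearly degenerate along a (lM0, lTs) ribbon: both
  # raise or lower the simulated normalized fiber length, and only the
  # excursion amplitude separates them, so a descent started far off can
  # settle on the wrong side. A coarse grid fit of the two ratios per
  # tracked muscle - holding the warm-start tendon kinematics fixed -
  # selects the right basin before the joint refinement.
  theta0_grid <- function(ltt_b) {
    grid <- seq(1 - spec$lm0_frac, 1 + spec$lm0_frac, by = 0.005)
    gridT <- seq(1 - spec$lts_frac, 1 + spec$lts_frac, by = 0.005)
    th_lm0 <- th_lts <- numeric(np)
    for (k in seq_len(np)) {
      n <- idx[k]
      lmt <- mm$lmt[, n]
      lt_b <- ltt_b[, n] * base$lTs[n]
      ref <- ref_mat[, k]
      best <- c(Inf, 1, 1)
      for (rT in gridT) {
        proj <- lmt - rT * lt_b
        for (rL in grid) {
          h <- rL * base$lM0[n] * sin(base$theta0[n])
          lmv <- sqrt(pmax(proj, 0.02 * base$lM0[n])^2 + h^2) /
            (rL * base$lM0[n])
          err <- sum((lmv - ref)^2)
          if (err < best[1]) best <- c(err, rL, rT)
        }
      }
      th_lm0[k] <- best[2]
      th_lts[k] <- best[3]
    }
    list(lm0 = th_lm0, lts = th_lts)
  }
  # Joint optimization of the trajectories and the tuned parameters in one
  # box-constrained least-squares problem: damped Gauss-Newton with the
  # sparse stencil-colored Jacobian (plus dense parameter columns).
  track <- list(idx = idx, ref = ref_mat)
  unpack_theta <- function(th) {
    mus <- base
    mus$lM0[idx] <- base$lM0[idx] * th[seq_len(np)]
    mus$lTs[idx] <- base$lTs[idx] * th[np + seq_len(np)]
    mus$kT[idx] <- 35 * th[2 * np + seq_len(np)]
    mus
  }
  fn <- function(par) {
    mus <- unpack_theta(par[npar_traj + seq_len(3 * np)])
    ev <- eval_compliant(matrix(par[seq_len(npar_traj)], nt), mus, mm, config)
    c(traj_residuals(ev, weights, config, wt, track)$resid, agg_resid(mus))
  }
  jac <- make_sparse_jac(fn, nt, nrow(base), length(mm$joints),
                         tracked_idx = idx, n_param = 3 * np, n_tail = 1)
  b <- ftt_bounds(base, nt)
  ftt0 <- base_fit$ft / row_mat(base$F0, nt)
  th0 <- theta0_grid(base_fit$lt_tilde)
  par0 <- c(as.vector(pmin(pmax(ftt0, b$lower + 0.01), b$upper - 0.01)),
            th0$lm0, th0$lts, start$kT[idx] / 35)
  lower <- c(b$lower,
             rep(1 - spec$lm0_frac, np), rep(1 - spec$lts_frac, np),
             rep(spec$kt_bounds[1] / 35, np))
  upper <- c(b$upper,
             rep(1 + spec$lm0_frac, np), rep(1 + spec$lts_frac, np),
             rep(spec$kt_bounds[2] / 35, np))
  ctrl <- minpack.lm::nls.lm.control(maxiter = max(config$maxiter, 300),
                                     ftol = 1e-13, ptol = 1e-11, gtol = 0,
                                     maxfev = 1000000L)
  out <- minpack.lm::nls.lm(par = par0, fn = fn, jac = jac,
                            lower = lower, upper = upper, control = ctrl)
  out$converged <- out$info %in% 1:4
  out$objective <- sum(out$fvec^2)
  tuned_mus <- unpack_theta(out$par[npar_traj + seq_len(3 * np)])

  # project the aggregate stiffness exactly into its band, then re-solve the
  # trajectories with the parameters frozen
  agg <- achilles_aggregate(tuned_mus, spec$achilles)
  # pinned at a band edge (the penalty is holding it there) counts as active
  constraint_active <- min(abs(agg - spec$achilles_bounds)) < 1e-3
  if (agg > spec$achilles_bounds[2] || agg < spec$achilles_bounds[1]) {
    constraint_active <- TRUE
    bound <- min(max(agg, spec$achilles_bounds[1]), spec$achilles_bounds[2])
    tuned_mus$kT[ach_idx] <- pmin(pmax(tuned_mus$kT[ach_idx] * bound / agg,
                                       spec$kt_bounds[1]), spec$kt_bounds[2])
    agg <- achilles_aggregate(tuned_mus, spec$achilles)
  }
  final <- solve_redundancy(motion, tuned_mus, weights, config)

  rmse <- sapply(seq_along(idx), function(k) {
    sqrt(mean((final$lm_tilde[, idx[k]] - ref_mat[, k])^2))
  })
  rmse_base <- sapply(seq_along(idx), function(k) {
    sqrt(mean((base_fit$lm_tilde[, idx[k]] - ref_mat[, k])^2))
  })
  tuned <- tibble::tibble(
    name = tracked,
    lM0 = tuned_mus$lM0[idx], lM0_baseline = base$lM0[idx],
    lTs = tuned_mus$lTs[idx], lTs_baseline = base$lTs[idx],
    kT = tuned_mus$kT[idx], kT_baseline = base$kT[idx],
    tracking_rmse = rmse, tracking_rmse_baseline = rmse_base
  )
  structure(list(
    params = tuned_mus, tuned = tuned, baseline = base,
    solution = final, refs = refs, ref_mat = ref_mat, tracked = tracked,
    aggregate_stiffness_n_mm = agg, constraint_active = constraint_active,
    spec = spec, weights = weights, config = config,
    solver = list(converged = out$converged, message = out$message,
                  niter = out$niter, objective = out$objective)
  ), class = "fiber_tuning_fit")
}

#' @export
print.fiber_tuning_fit <- function(x, ...) {
  cat("<fiber_tuning_fit> ", length(x$tracked), " tracked muscles, ",
      "aggregate Achilles stiffness ",
      format(x$aggregate_stiffness_n_mm, digits = 5), " N/mm",
      if (x$constraint_active) " (constraint active)", "\n", sep = "")
  print(x$tuned)
  invisible(x)
}
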