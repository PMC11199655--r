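# Per-trial motion inputs: a wide table on a common time grid.
#
# Column layout: `time` (s, strictly increasing), `q_<joint>` joint angles
# (rad), `tau_<joint>` net joint moments from inverse dynamics (N m),
# `lmt_<muscle>` muscle-tendon lengths (m), optional `vmt_<muscle>`
# muscle-tendon velocities (m/s, computed by finite differences when absent),
# and `arm_<muscle>_<joint>` moment arms (m). Moment arms may be constant or
# time-varying; a missing arm column means the muscle does not span the joint.

motion_joints <- function(motion) {
  sub("^q_", "", grep("^q_", names(motion), value = TRUE))
}

motion_muscles <- function(motion) {
  sub("^lmt_", "", grep("^lmt_", names(motion), value = TRUE))
}

#' Validate a motion-inputs table
#'
#' Checks the wide motion table layout: a strictly increasing `time` column,
#' matching `q_`/`tau_` joint columns, positive `lmt_` muscle-tendon lengths,
#' and congruent column lengths. When a muscle parameter table is given, every
#' muscle must have an `lmt_` column.
#'
#' @param motion A wide motion table (see the package vignette for the layout).
#' @param muscles Optional [muscle_params()] table to cross-check against.
#' @return The validated table, invisibly as a tibble.
#' @export
validate_motion <- function(motion, muscles = NULL) {
  motion <- tibble::as_tibble(motion)
  if (!"time" %in% names(motion)) stop("motion table needs a `time` column",
                                       call. = FALSE)
  if (any(diff(motion$time) <= 0)) stop("`time` must be strictly increasing",
                                        call. = FALSE)
  joints <- motion_joints(motion)
  if (!length(joints)) stop("no `q_<joint>` columns found", call. = FALSE)
  missing_tau <- setdiff(paste0("tau_", joints), names(motion))
  if (length(missing_tau)) {
    stop("missing joint moment columns: ", paste(missing_tau, collapse = ", "),
         call. = FALSE)
  }
  mus <- motion_muscles(motion)
  if (!length(mus)) stop("no `lmt_<muscle>` columns found", call. = FALSE)
  lmt <- as.matrix(motion[paste0("lmt_", mus)])
  if (any(lmt <= 0)) stop("muscle-tendon lengths must be positive",
                          call. = FALSE)
  if (!is.null(muscles)) {
    absent <- setdiff(muscles$name, mus)
    if (length(absent)) {
      stop("motion table lacks lmt columns for: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  invisible(motion)
}

# Convert a validated motion table into the matrix bundle used by the solver.
motion_matrices <- function(motion, muscle_names = NULL) {
  motion <- validate_motion(motion)
  joints <- motion_joints(motion)
  mus <- muscle_names %||% motion_muscles(motion)
  t <- motion$time
  nt <- length(t)
  q <- as.matrix(motion[paste0("q_", joints)])
  tau <- as.matrix(motion[paste0("tau_", joints)])
  lmt <- as.matrix(motion[paste0("lmt_", mus)])
  vmt_cols <- paste0("vmt_", mus)
  vmt <- if (all(vmt_cols %in% names(motion))) {
    as.matrix(motion[vmt_cols])
  } else {
    apply(lmt, 2, grad_central, t = t)
  }
  arm <- array(0, dim = c(nt, length(mus), length(joints)),
               dimnames = list(NULL, mus, joints))
  for (j in seq_along(joints)) {
    for (m in seq_along(mus)) {
      col <- paste0("arm_", mus[m], "_", joints[j])
      if (col %in% names(motion)) arm[, m, j] <- motion[[col]]
    }
  }
  colnames(q) <- colnames(tau) <- joints
  colnames(lmt) <- colnames(vmt) <- mus
  list(time = t, joints = joints, muscles = mus,
       q = q, tau = tau, lmt = lmt, vmt = vmt, arm = arm)
}

# Central finite differences on a (possibly non-uniform) grid, one-sided at
# the ends.
grad_central <- function(x, t) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / (t[2] - t[1])
  g[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  g
}

#' Resample a motion table onto a uniform grid
#'
#' Linear interpolation of every column onto `n` uniformly spaced time points
#' spanning the trial.
#'
#' @inheritParams validate_motion
#' @param n Number of output time points.
#' @return A tibble with the same columns on the new grid.
#' @export
resample_motion <- function(motion, n) {
  motion <- validate_motion(motion)
  t_new <- seq(motion$time[1], motion$time[nrow(motion)], length.out = n)
  out <- purrr::map(motion, function(col) {
    stats::approx(motion$time, col, xout = t_new)$y
  })
  out$time <- t_new
  tibble::as_tibble(out)
}
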