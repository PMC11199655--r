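# Static (zero-activation, zero-velocity) muscle-tendon evaluation and the
# passive moment-angle trial machinery.

#' Solve the static fiber-tendon equilibrium
#'
#' For given activation, muscle-tendon length and parameters, finds the
#' normalized tendon length at which the fiber force (evaluated at zero fiber
#' velocity) projected through the pennation angle equals the tendon force.
#' The residual is strictly decreasing in normalized tendon length, so the
#' root is unique and found by bisection; if the root lies outside the
#' bracket (a fully slack or fully stretched configuration) the nearest
#' bracket edge is returned.
#'
#' @param muscles A [muscle_params()] table.
#' @param lmt Muscle-tendon lengths: a vector (one per muscle) or a
#'   `K x N` matrix of `K` postures by `N` muscles.
#' @param a Activation, scalar or same shape as `lmt` (default 0).
#' @param iters Bisection iterations (default 60, resolving lt_tilde to
#'   about 1e-18 over the bracket).
#' @return A list of matrices (`lt_tilde`, `lm_tilde`, `cos_theta`,
#'   `ft` tendon force in N).
#' @export
static_equilibrium <- function(muscles, lmt, a = 0, iters = 60) {
  muscles <- muscle_params(muscles)
  if (is.null(dim(lmt))) lmt <- matrix(lmt, nrow = 1)
  k <- nrow(lmt)
  n <- nrow(muscles)
  stopifnot(ncol(lmt) == n)
  if (length(a) == 1) a <- matrix(a, k, n)
  lm0 <- row_mat(muscles$lM0, k)
  lts <- row_mat(muscles$lTs, k)
  th0 <- row_mat(muscles$theta0, k)
  kt <- row_mat(muscles$kT, k)
  kpe <- row_mat(muscles$kPE, k)
  s0 <- row_mat(muscles$s0, k)
  sm <- row_mat(muscles$sM, k)
  resid <- function(ltt) {
    geo <- fiber_geometry(lmt, ltt * lts, lm0, th0)
    fl <- .fl_raw(geo$lm_tilde) / .fl_at_one
    fpas <- passive_force(geo$lm_tilde, kpe, s0, sm)
    (a * fl + fpas) * geo$cos_theta - tendon_force(ltt, kt)
  }
  lo <- matrix(0.5, k, n)
  hi <- pmax(pmin((lmt - 0.02 * lm0) / lts, 1.15), 0.5 + 1e-9)
  r_lo <- resid(lo)
  r_hi <- resid(hi)
  at_hi <- r_hi >= 0 # root beyond maximal stretch: pin at the edge
  at_lo <- r_lo <= 0
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    pos <- resid(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  ltt <- 0.5 * (lo + hi)
  ltt[at_hi] <- pmax(pmin((lmt - 0.02 * lm0) / lts, 1.15), 0.5)[at_hi]
  ltt[at_lo] <- 0.5
  geo <- fiber_geometry(lmt, ltt * lts, lm0, th0)
  list(lt_tilde = ltt, lm_tilde = geo$lm_tilde, cos_theta = geo$cos_theta,
       ft = row_mat(muscles$F0, k) * tendon_force(ltt, kt))
}

#' Construct a passive moment-angle trial
#'
#' One passive sweep: a swept joint moved across its range of motion while the
#' other joints are held at a fixed posture, with the muscle-tendon lengths
#' and moment arms of every muscle at each sweep posture and (optionally) the
#' measured passive moments.
#'
#' @param joint Name of the swept joint.
#' @param angles Sweep angles (rad), strictly monotone.
#' @param q_fixed Named vector of fixed angles of the other joints (rad).
#' @param lmt `K x N` matrix of muscle-tendon lengths at each sweep posture.
#' @param arm `K x N` matrix of moment arms about the swept joint.
#' @param moment Measured passive moments (N m), length `K`, or `NULL`.
#' @return An object of class `passive_trial`.
#' @export
passive_trial <- function(joint, angles, q_fixed, lmt, arm, moment = NULL) {
  stopifnot(all(diff(angles) > 0) || all(diff(angles) < 0))
  stopifnot(nrow(lmt) == length(angles), nrow(arm) == length(angles))
  if (!is.null(moment)) stopifnot(length(moment) == length(angles))
  structure(list(joint = joint, angles = angles, q_fixed = q_fixed,
                 lmt = lmt, arm = arm, moment = moment),
            class = "passive_trial")
}

#' @export
print.passive_trial <- function(x, ...) {
  cat("<passive_trial> swept:", x$joint, "(", length(x$angles), "angles ),",
      "fixed:", paste(names(x$q_fixed), round(x$q_fixed * 180 / pi, 1),
                      "deg", collapse = ", "), "\n")
  invisible(x)
}

#' Predict passive joint moments for a trial
#'
#' Static passive evaluation: at every sweep posture each muscle's
#' fiber-tendon equilibrium is solved with zero activation and zero fiber
#' velocity, so only the passive fiber force loads the tendon; tendon forces
#' are projected through the moment arms and summed over muscles.
#'
#' @param trial A [passive_trial()].
#' @param muscles A [muscle_params()] table (columns `kPE`, `s0`, `sM` carry
#'   the passive parameters being evaluated).
#' @return A tibble with columns `angle` (rad) and `moment` (N m).
#' @export
predict_passive_moments <- function(trial, muscles) {
  eq <- static_equilibrium(muscles, trial$lmt, a = 0)
  tibble::tibble(angle = trial$angles,
                 moment = rowSums(trial$arm * eq$ft))
}

# The default passive sweep protocol: swept joint, fixed posture (degrees) of
# the other joints, for the eight standard trial configurations (three ankle
# sweeps at increasing knee flexion, three knee sweeps at combinations of
# ankle dorsi-/plantarflexion and hip extension, two hip sweeps at two knee
# flexion angles).
passive_protocol_postures <- function() {
  list(
    list(joint = "ankle", fixed = c(knee = 0, hip = 0)),
    list(joint = "ankle", fixed = c(knee = 15, hip = 0)),
    list(joint = "ankle", fixed = c(knee = 60, hip = 0)),
    list(joint = "knee", fixed = c(ankle = 20, hip = 0)),
    list(joint = "knee", fixed = c(ankle = -15, hip = 0)),
    list(joint = "knee", fixed = c(ankle = 20, hip = -15)),
    list(joint = "hip", fixed = c(knee = 15, ankle = 0)),
    list(joint = "hip", fixed = c(knee = 60, ankle = 0))
  )
}

#' Build the eight-trial passive sweep protocol
#'
#' Builds the standard passive moment-angle protocol: ankle sweeps at 0, 15
#' and 60 degrees knee flexion; knee sweeps at 20 degrees dorsiflexion with
#' the hip neutral, 15 degrees plantarflexion with the hip neutral, and 20
#' degrees dorsiflexion with 15 degrees hip extension; and hip sweeps at 15
#' and 60 degrees knee flexion. Joint angle conventions: ankle positive in
#' dorsiflexion, knee positive in flexion, hip positive in flexion.
#'
#' @param geometry A geometry provider: `function(q)` mapping a named posture
#'   vector (rad) to `list(lmt = <named vector>, arm = <muscle x joint
#'   matrix>)`, as returned by [toy_geometry()].
#' @param joints Names of the model joints; must contain ankle, knee, hip.
#' @param sweep Named list of sweep ranges in degrees,
#'   `list(ankle = c(lo, hi), knee = ..., hip = ...)`.
#' @param n_angles Number of sweep postures per trial (default 15).
#' @return A list of eight [passive_trial()] objects (moments unset).
#' @export
build_passive_protocol <- function(geometry,
                                   joints = c("ankle", "knee", "hip"),
                                   sweep = list(ankle = c(-30, 30),
                                                knee = c(0, 70),
                                                hip = c(-20, 45)),
                                   n_angles = 15) {
  need <- c("ankle", "knee", "hip")
  if (!all(need %in% joints)) {
    stop("the passive protocol needs ankle, knee and hip joints",
         call. = FALSE)
  }
  deg <- pi / 180
  purrr::map(passive_protocol_postures(), function(p) {
    angles <- seq(sweep[[p$joint]][1], sweep[[p$joint]][2],
                  length.out = n_angles) * deg
    fixed <- p$fixed * deg
    rows <- purrr::map(angles, function(ang) {
      q <- stats::setNames(numeric(length(joints)), joints)
      q[names(fixed)] <- fixed
      q[p$joint] <- ang
      g <- geometry(q)
      list(lmt = g$lmt, arm = g$arm[, p$joint])
    })
    passive_trial(
      joint = p$joint, angles = angles, q_fixed = fixed,
      lmt = do.call(rbind, purrr::map(rows, "lmt")),
      arm = do.call(rbind, purrr::map(rows, "arm"))
    )
  })
}

#' Shorten a tendon slack length until the fiber stays feasible
#'
#' Some linearly scaled models leave a muscle (classically the
#' semimembranosus) with a tendon slack length so long that its fiber length
#' would be non-positive at extreme protocol postures. This returns the
#' muscle table with the smallest decrease of that muscle's slack length such
#' that the projected fiber length is at least `floor` optimal fiber lengths
#' at every posture of the protocol; the table is unchanged if the muscle is
#' already feasible everywhere, and the adjustment is idempotent.
#'
#' @param muscles A [muscle_params()] table.
#' @param protocol A list of [passive_trial()] objects.
#' @param muscle Name of the muscle to adjust (default `"semimem"`).
#' @param floor Minimum admissible projected fiber length, in units of the
#'   optimal fiber length (default 0.1).
#' @return The muscle table, with `lTs` of `muscle` possibly reduced.
#' @export
fix_slack_length <- function(muscles, protocol, muscle = "semimem",
                             floor = 0.1) {
  muscles <- muscle_params(muscles)
  i <- match(muscle, muscles$name)
  if (is.na(i)) stop("unknown muscle: ", muscle, call. = FALSE)
  lmt_min <- min(purrr::map_dbl(protocol, function(tr) min(tr$lmt[, i])))
  need <- floor * muscles$lM0[i] * cos(muscles$theta0[i])
  lts_max <- lmt_min - need
  if (lts_max <= 0) {
    stop("no feasible slack length > 0 for ", muscle, call. = FALSE)
  }
  if (muscles$lTs[i] > lts_max) muscles$lTs[i] <- lts_max
  muscles
}
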