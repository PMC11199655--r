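# Characteristic curves of the Hill-type muscle-tendon actuator.
#
# Curve families and coefficients follow the widely used smooth formulation of
# De Groote and colleagues: a three-Gaussian active force-length curve, a
# log/sinh force-velocity curve, an exponential tendon force-strain curve whose
# offset is recalibrated per tendon stiffness so force is exactly zero at slack
# length, and the exponential passive fiber force-length relationship
# parameterized by (kPE, s0, sM).

# Active force-length Gaussian coefficients (rows: b1 amplitude, b2 center,
# b3 width, b4 width slope).
.fl_coef <- matrix(
  c(0.814483478343008, 1.055033428970575, 0.162384573599574, 0.063303448465465,
    0.433004984392647, 0.716775413397760, -0.029947116970696, 0.200356847296188,
    0.100000000000000, 1.000000000000000, 0.353553390593274, 0.000000000000000),
  nrow = 3, byrow = TRUE
)

# Force-velocity coefficients d1..d4 (log/sinh form).
.fv_coef <- c(-0.318323436899127, -8.149156043475250,
              -0.374121508647863, 0.885644059915004)

# Tendon curve scale and reference strain; the offset c3 is recomputed per kT.
.ft_c1 <- 0.2
.ft_c2 <- 0.995

.fl_raw <- function(lm_tilde) {
  b <- .fl_coef
  val <- 0
  for (i in 1:3) {
    width <- b[i, 3] + b[i, 4] * lm_tilde
    val <- val + b[i, 1] * exp(-0.5 * ((lm_tilde - b[i, 2]) / width)^2)
  }
  val
}

.fl_at_one <- .fl_raw(1)

.fv_raw <- function(vm_tilde) {
  d <- .fv_coef
  z <- d[2] * vm_tilde + d[3]
  d[1] * log(z + sqrt(z^2 + 1)) + d[4]
}

.fv_at_zero <- .fv_raw(0)

.check_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop("non-finite values in `", name, "`", call. = FALSE)
  }
  invisible(x)
}

#' Passive fiber force-length multiplier
#'
#' Exponential passive force-length relationship of the muscle fiber,
#' \deqn{f_{pas}(\tilde{l}_M) = \frac{e^{k_{PE}(\tilde{l}_M - s_0)/s_M} - 1}
#'   {e^{k_{PE}} - 1},}
#' where `s0` is the normalized fiber length at which passive force starts to
#' rise and `s0 + sM` the normalized fiber length at which it reaches 1.
#' The curve is negative below `s0` by construction; set `clamp = TRUE` to
#' clamp it at zero for formulations that forbid compressive passive force.
#'
#' @param lm_tilde Normalized fiber length (fiber length / optimal fiber
#'   length), any numeric vector.
#' @param kpe Exponential shape factor (> 0), default 4.
#' @param s0 Normalized fiber length where passive force rises, default 1.
#' @param sm Normalized width of the passive curve (> 0), default 0.6.
#' @param clamp If `TRUE`, negative values (below `s0`) are clamped to zero.
#' @return Dimensionless passive force multiplier, same length as `lm_tilde`.
#' @examples
#' passive_force(c(1, 1.3, 1.6))
#' @export
passive_force <- function(lm_tilde, kpe = 4, s0 = 1, sm = 0.6, clamp = FALSE) {
  .check_finite(lm_tilde, "lm_tilde")
  .check_finite(c(kpe, s0, sm), "passive parameters")
  stopifnot(all(kpe > 0), all(sm > 0))
  f <- (exp(kpe * (lm_tilde - s0) / sm) - 1) / (exp(kpe) - 1)
  if (clamp) f <- pmax(f, 0)
  f
}

#' Active force-length multiplier
#'
#' Sum-of-Gaussians active force-length curve, normalized so that its value at
#' the optimal fiber length (`lm_tilde = 1`) is exactly 1.
#'
#' @inheritParams passive_force
#' @return Dimensionless active force multiplier in (0, 1].
#' @export
active_force_length <- function(lm_tilde) {
  .check_finite(lm_tilde, "lm_tilde")
  stopifnot(all(lm_tilde > 0))
  .fl_raw(lm_tilde) / .fl_at_one
}

#' Force-velocity multiplier and its inverse
#'
#' Monotonically increasing force-velocity curve on normalized fiber velocity
#' (in optimal fiber lengths per second divided by `vmax`; shortening
#' negative), normalized so the isometric value (`vm_tilde = 0`) is exactly 1.
#' `inverse_force_velocity()` returns the normalized velocity producing a given
#' multiplier; the two compose to the identity.
#'
#' @param vm_tilde Normalized fiber velocity (shortening negative).
#' @return Dimensionless force multiplier (`force_velocity`) or normalized
#'   velocity (`inverse_force_velocity`).
#' @export
force_velocity <- function(vm_tilde) {
  .check_finite(vm_tilde, "vm_tilde")
  .fv_raw(vm_tilde) / .fv_at_zero
}

#' @rdname force_velocity
#' @param multiplier Force-velocity multiplier to invert.
#' @export
inverse_force_velocity <- function(multiplier) {
  .check_finite(multiplier, "multiplier")
  d <- .fv_coef
  f <- multiplier * .fv_at_zero
  (sinh((f - d[4]) / d[1]) - d[3]) / d[2]
}

#' Tendon force-strain multiplier
#'
#' Exponential tendon curve \eqn{f_T = c_1 e^{k_T(\tilde{l}_T - c_2)} - c_3}
#' with the offset \eqn{c_3} recomputed for each normalized stiffness `kt` so
#' that the force is exactly zero at the slack length (`lt_tilde = 1`). The
#' curve is strictly increasing in `lt_tilde` and, above slack length,
#' pointwise increasing in `kt`.
#'
#' @param lt_tilde Normalized tendon length (tendon length / slack length).
#' @param kt Normalized tendon stiffness (dimensionless, > 0); the convention
#'   used for generic compliant Achilles tendons is 15 and for stiff tendons 35.
#' @return Dimensionless tendon force multiplier.
#' @export
tendon_force <- function(lt_tilde, kt) {
  .check_finite(lt_tilde, "lt_tilde")
  stopifnot(all(kt > 0))
  .ft_c1 * (exp(kt * (lt_tilde - .ft_c2)) - exp(kt * (1 - .ft_c2)))
}

# Inverse of the tendon curve: normalized tendon length at a given multiplier.
tendon_length_from_force <- function(ft, kt) {
  arg <- ft / .ft_c1 + exp(kt * (1 - .ft_c2))
  stopifnot(all(arg > 0))
  .ft_c2 + log(arg) / kt
}

#' Cosine of the pennation angle under the constant-thickness model
#'
#' The muscle belly is assumed to keep a constant height
#' \eqn{h = l_M^0 \sin\theta_0}, so \eqn{\sin\theta = \sin\theta_0/\tilde{l}_M}
#' and the force projection onto the tendon line of action is
#' \eqn{\cos\theta = \sqrt{1 - (\sin\theta_0/\tilde{l}_M)^2}}.
#'
#' @inheritParams passive_force
#' @param lm0 Optimal fiber length (m); present for interface symmetry, the
#'   projection depends only on `lm_tilde` and `theta0`.
#' @param theta0 Pennation angle at optimal fiber length (rad, in `[0, pi/2)`).
#' @return `cos(theta)` in (0, 1].
#' @export
pennation_cos <- function(lm_tilde, lm0 = NULL, theta0 = 0) {
  .check_finite(lm_tilde, "lm_tilde")
  stopifnot(all(theta0 >= 0), all(theta0 < pi / 2))
  s <- sin(theta0) / lm_tilde
  if (any(s >= 1)) {
    stop("fiber shorter than the constant muscle height: lm_tilde <= sin(theta0)",
         call. = FALSE)
  }
  sqrt(1 - s^2)
}

#' Fiber-tendon force equilibrium residual
#'
#' Residual of the equilibrium between the fiber force projected onto the
#' tendon and the tendon force,
#' \deqn{F^0 (a f_{act} f_v + f_{pas} + \beta \tilde{v}_M)\cos\theta -
#'   F^0 f_T(\tilde{l}_T),}
#' in newtons; zero at equilibrium.
#'
#' @param state A list or one-row data frame with elements `a`, `lm_tilde`,
#'   `vm_tilde` and `lt_tilde`.
#' @param params A one-row muscle parameter table (see [muscle_params()]).
#' @param damping Dimensionless fiber damping coefficient on normalized
#'   velocity (default 0.1).
#' @return Force residual (N); vectorized over the state elements.
#' @export
equilibrium_residual <- function(state, params, damping = 0.1) {
  cos_theta <- pennation_cos(state$lm_tilde, params$lM0, params$theta0)
  fiber <- state$a * active_force_length(state$lm_tilde) *
    force_velocity(state$vm_tilde) +
    passive_force(state$lm_tilde, params$kPE, params$s0, params$sM) +
    damping * state$vm_tilde
  params$F0 * (fiber * cos_theta - tendon_force(state$lt_tilde, params$kT))
}

#' Activation dynamics right-hand side
#'
#' Smooth first-order excitation-to-activation dynamics with a faster
#' activation than deactivation time constant, blended by a `tanh` switch so
#' the right-hand side is differentiable everywhere. The derivative is zero
#' when excitation equals activation.
#'
#' @param excitation Neural excitation in `[0, 1]`.
#' @param a Activation in `[0, 1]`.
#' @param tau_act Activation time constant (s), default 0.015.
#' @param tau_deact Deactivation time constant (s), default 0.060.
#' @param b Smoothing steepness of the activation/deactivation switch.
#' @return `da/dt` (1/s), vectorized.
#' @export
activation_dynamics_rhs <- function(excitation, a,
                                    tau_act = 0.015, tau_deact = 0.060,
                                    b = 0.1) {
  .check_finite(c(excitation, a), "excitation/activation")
  f <- 0.5 * tanh(b * (excitation - a))
  rate <- (f + 0.5) / (tau_act * (0.5 + 1.5 * a)) +
    (0.5 - f) * (0.5 + 1.5 * a) / tau_deact
  rate * (excitation - a)
}

# Invert the activation dynamics: excitation that produces a given da/dt at
# activation a. Monotone in excitation; solved by bisection on [0, 1] and
# clamped to the admissible excitation range.
excitation_from_dynamics <- function(dadt, a, tau_act = 0.015,
                                     tau_deact = 0.060, b = 0.1) {
  n <- max(length(dadt), length(a))
  dadt <- rep_len(dadt, n)
  a <- rep_len(a, n)
  lo <- rep(0, n)
  hi <- rep(1, n)
  g <- function(e) activation_dynamics_rhs(e, a, tau_act, tau_deact, b) - dadt
  g_lo <- g(lo)
  g_hi <- g(hi)
  out_lo <- g_lo >= 0 # even full relaxation decays faster than requested
  out_hi <- g_hi <= 0 # even full drive cannot rise as fast as requested
  for (i in 1:60) {
    mid <- 0.5 * (lo + hi)
    pos <- g(mid) > 0
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
  }
  e <- 0.5 * (lo + hi)
  e[out_lo] <- 0
  e[out_hi] <- 1
  e
}
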