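# Muscle metabolic energetics: per-muscle metabolic rate from activation,
# maintenance and shortening heat plus mechanical work of the contractile
# element (Bhargava-style model), with a heat-rate adjustment that keeps the
# total rate non-negative; leg aggregation; whole-body averaging with a basal
# rate; and the indirect-calorimetry (Brockway) conversion.

#' Metabolic model parameters
#'
#' Muscle masses are derived from the architecture,
#' `m = F0 / sigma * lM0 * rho`, with specific tension `sigma` (default
#' 60 N/cm2) and muscle density `rho` (default 1059.7 kg/m3). Heat-rate
#' coefficients (W/kg) follow the Bhargava-style partition into slow- and
#' fast-twitch activation and maintenance heat; the shortening-heat constants
#' scale the isometric and actual contractile-element force during shortening
#' and the actual force during lengthening.
#'
#' @param body_mass Whole-body mass (kg).
#' @param basal Basal whole-body rate (W/kg), default 1.2.
#' @param specific_tension Specific tension (N/cm2), default 60.
#' @param density Muscle density (kg/m3), default 1059.7.
#' @param act_coef Activation heat coefficients `c(slow, fast)` (W/kg).
#' @param maint_coef Maintenance heat coefficients `c(slow, fast)` (W/kg).
#' @param short_coef Shortening/lengthening heat constants
#'   `c(iso, shortening, lengthening)`.
#' @return A named list.
#' @export
metabolic_params <- function(body_mass, basal = 1.2, specific_tension = 60,
                             density = 1059.7,
                             act_coef = c(slow = 40, fast = 133),
                             maint_coef = c(slow = 74, fast = 111),
                             short_coef = c(iso = 0.16, shortening = 0.18,
                                            lengthening = 0.157)) {
  stopifnot(body_mass > 0, basal >= 0, specific_tension > 0, density > 0)
  list(body_mass = body_mass, basal = basal,
       specific_tension = specific_tension, density = density,
       act_coef = act_coef, maint_coef = maint_coef, short_coef = short_coef)
}

# Mass of each muscle (kg) from architecture and specific tension.
muscle_mass <- function(muscles, met) {
  pcsa <- muscles$F0 / (met$specific_tension * 1e4) # m2
  pcsa * muscles$lM0 * met$density
}

# Piecewise-linear dependence of the maintenance heat on normalized fiber
# length: 0.5 below half the optimal length, 1 around the optimum, dropping
# to 0 at twice the optimal length.
maintenance_length_factor <- function(lm_tilde) {
  x <- c(0, 0.5, 1.0, 1.5, 2.0)
  y <- c(0.5, 0.5, 1.0, 1.0, 0.0)
  v <- stats::approx(x, y, xout = pmin(pmax(as.vector(lm_tilde), 0), 2),
                     rule = 2)$y
  if (is.matrix(lm_tilde)) matrix(v, nrow(lm_tilde)) else v
}

#' Per-muscle metabolic rates of a solved trial
#'
#' Computes, for every muscle and mesh point of a redundancy solution, the
#' activation heat rate, maintenance heat rate, shortening/lengthening heat
#' rate and the mechanical work rate of the contractile element, in watts.
#' When the raw sum is negative (eccentric phases where negative work exceeds
#' the heat rates) the heat dissipation is adjusted so the reported total is
#' exactly zero, keeping the metabolic rate non-negative everywhere.
#'
#' @param fit A `redundancy_fit` from [solve_redundancy()].
#' @param met [metabolic_params()].
#' @param use_excitation Use the recovered excitations for the activation and
#'   maintenance recruitment terms (default); otherwise activations are used.
#' @return An object of class `metabolic_trace`: time and percent-cycle
#'   grids, the per-muscle rate matrix (`rate`, W, adjusted), the unadjusted
#'   matrix (`rate_raw`), the leg rate (`leg`) and the metabolic parameters.
#'   Use [tidy()]/[glance()] or [leg_rate()] and [whole_body_average()].
#' @export
muscle_metabolic_rates <- function(fit, met, use_excitation = TRUE) {
  stopifnot(inherits(fit, "redundancy_fit"))
  mus <- fit$muscles
  nt <- length(fit$time)
  m <- row_mat(muscle_mass(mus, met), nt)
  fs <- row_mat(mus$slow_twitch_fraction, nt)
  ff <- 1 - fs
  u <- if (use_excitation) fit$excitation else fit$a
  u_slow <- sin(pi / 2 * u)
  u_fast <- 1 - cos(pi / 2 * u)
  adot <- m * (met$act_coef[["slow"]] * fs * u_slow +
                 met$act_coef[["fast"]] * ff * u_fast)
  mdot <- m * maintenance_length_factor(fit$lm_tilde) *
    (met$maint_coef[["slow"]] * fs * u_slow +
       met$maint_coef[["fast"]] * ff * u_fast)
  fl <- .fl_raw(fit$lm_tilde) / .fl_at_one
  fv <- pmax(.fv_raw(fit$vm_tilde) / .fv_at_zero, 0)
  f0m <- row_mat(mus$F0, nt)
  f_iso <- fit$a * fl * f0m
  f_ce <- fit$a * fl * fv * f0m
  vm <- fit$vm_tilde * row_mat(mus$vmax * mus$lM0, nt) # m/s, shortening < 0
  alpha <- ifelse(vm <= 0,
                  met$short_coef[["iso"]] * f_iso +
                    met$short_coef[["shortening"]] * f_ce,
                  met$short_coef[["lengthening"]] * f_ce)
  sdot <- -alpha * vm
  wdot <- -f_ce * vm
  raw <- adot + mdot + sdot + wdot
  rate <- pmax(raw, 0)
  dimnames(rate) <- dimnames(raw) <- list(NULL, mus$name)
  structure(list(time = fit$time, pct = fit$pct, muscles = mus$name,
                 rate = rate, rate_raw = raw,
                 components = list(activation = adot, maintenance = mdot,
                                   shortening = sdot, work = wdot),
                 leg = rowSums(rate), met = met),
            class = "metabolic_trace")
}

#' @export
print.metabolic_trace <- function(x, ...) {
  avg <- whole_body_average(x$leg, x$met$body_mass, x$met$basal, x$time)
  cat("<metabolic_trace> ", length(x$muscles), " muscles; net ",
      format(avg$net_w_kg, digits = 4), " W/kg, gross ",
      format(avg$gross_w_kg, digits = 4), " W/kg\n", sep = "")
  invisible(x)
}

#' Metabolic rate of one leg
#'
#' Pointwise sum of the per-muscle metabolic rates,
#' \eqn{\dot{E}_{leg}(t) = \sum_n \dot{E}_n(t)}.
#'
#' @param rates A `metabolic_trace`, or a matrix/data frame of per-muscle
#'   rates (W) on a common time grid.
#' @return Numeric vector of leg rates (W).
#' @export
leg_rate <- function(rates) {
  if (inherits(rates, "metabolic_trace")) return(rowSums(rates$rate))
  rates <- as.matrix(rates)
  if (!is.numeric(rates)) stop("rates must be numeric", call. = FALSE)
  rowSums(rates)
}

#' Whole-body average metabolic rate
#'
#' The net whole-body average is the cycle-average leg rate multiplied by two
#' (both legs) and divided by body mass; the gross average adds the basal
#' rate.
#'
#' @param edot_leg Leg metabolic rate trace (W).
#' @param body_mass Body mass (kg).
#' @param basal Basal rate (W/kg), default 1.2.
#' @param time Optional time grid for trapezoidal cycle averaging; a plain
#'   mean is used when omitted.
#' @return A tibble with columns `net_w_kg` and `gross_w_kg`.
#' @export
whole_body_average <- function(edot_leg, body_mass, basal = 1.2,
                               time = NULL) {
  stopifnot(body_mass > 0)
  avg <- if (is.null(time)) {
    mean(edot_leg)
  } else {
    sum(trap_weights(time) * edot_leg) / diff(range(time))
  }
  net <- 2 * avg / body_mass
  tibble::tibble(net_w_kg = net, gross_w_kg = net + basal)
}

#' Energy rate from gas exchange (Brockway equation)
#'
#' Converts oxygen uptake and carbon dioxide production rates to a metabolic
#' energy rate, `(c_o2 * VO2 + c_co2 * VCO2)` kJ/min expressed in watts. The
#' default coefficients are the published values 16.58 kJ/L O2 and
#' 4.51 kJ/L CO2; both are configurable.
#'
#' @param vo2 Oxygen uptake (L/min).
#' @param vco2 Carbon dioxide production (L/min).
#' @param c_o2,c_co2 Energy equivalents (kJ/L).
#' @return Energy rate (W).
#' @examples
#' brockway_rate(0.3, 0.25)
#' @export
brockway_rate <- function(vo2, vco2, c_o2 = 16.58, c_co2 = 4.51) {
  stopifnot(all(vo2 >= 0), all(vco2 >= 0))
  (c_o2 * vo2 + c_co2 * vco2) * 1000 / 60
}

#' On/off timing of an excitation trace
#'
#' Intervals of the gait cycle where the excitation is at least 50% of its
#' maximum value, the rule used to compare simulated excitations with
#' electromyography. Contiguous runs of grid points at or above the threshold
#' are merged into intervals; a constant positive trace is "on" for the whole
#' cycle and an all-zero trace has no on-intervals.
#'
#' @param trace Excitation trace (non-negative).
#' @param pct Percent-gait-cycle grid (default: uniform 0-100).
#' @param threshold Fraction of the maximum (default 0.5).
#' @return A tibble with columns `start_pct`, `end_pct`, one row per
#'   on-interval.
#' @export
onoff_timing <- function(trace, pct = NULL, threshold = 0.5) {
  .check_finite(trace, "trace")
  if (is.null(pct)) pct <- seq(0, 100, length.out = length(trace))
  if (max(trace) <= 0) {
    return(tibble::tibble(start_pct = numeric(0), end_pct = numeric(0)))
  }
  on <- trace >= threshold * max(trace)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start_pct = pct[starts[keep]], end_pct = pct[ends[keep]])
}
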