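# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

resample_cols <- function(x, pct, n) {
  pct_out <- seq(0, 100, length.out = n)
  apply(x, 2, function(col) stats::approx(pct, col, xout = pct_out)$y)
}

#' Tidy a redundancy solution
#'
#' @param x A `redundancy_fit`.
#' @param n Number of percent-gait-cycle points the trajectories are
#'   resampled to for reporting (default 101).
#' @param ... Unused.
#' @return A long tibble with columns `pct`, `muscle`, `activation`,
#'   `excitation`, `lm_tilde`, `vm_tilde`, `lt_tilde`, `ft` and, per joint,
#'   the reserve excitation in a companion attribute-free long block
#'   (`reserves` component of [glance()] holds the summary).
#' @export
tidy.redundancy_fit <- function(x, n = 101, ...) {
  pct_out <- seq(0, 100, length.out = n)
  grab <- function(mat) as.vector(resample_cols(mat, x$pct, n))
  tibble::tibble(
    pct = rep(pct_out, nrow(x$muscles)),
    muscle = rep(x$muscles$name, each = n),
    activation = grab(x$a),
    excitation = grab(x$excitation),
    lm_tilde = grab(x$lm_tilde),
    vm_tilde = grab(x$vm_tilde),
    lt_tilde = grab(x$lt_tilde),
    ft = grab(x$ft)
  )
}

#' @rdname tidy.redundancy_fit
#' @export
glance.redundancy_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective$value,
    term_activation = x$objective$terms[["activation"]],
    term_reserve = x$objective$terms[["reserve"]],
    term_velocity = x$objective$terms[["velocity"]],
    term_tracking = x$objective$terms[["tracking"]],
    max_reserve_moment = x$diagnostics$max_reserve_moment,
    max_activation_violation = x$diagnostics$max_activation_violation,
    converged = x$solver$converged,
    mode = x$solver$mode
  )
}

#' Reserve excitations of a redundancy solution as a tibble
#'
#' @inheritParams tidy.redundancy_fit
#' @return Long tibble with columns `pct`, `joint`, `e_r`.
#' @export
tidy_reserves <- function(x, n = 101) {
  pct_out <- seq(0, 100, length.out = n)
  er <- resample_cols(x$e_r, x$pct, n)
  tibble::tibble(pct = rep(pct_out, length(x$joints)),
                 joint = rep(x$joints, each = n),
                 e_r = as.vector(er))
}

#' @rdname tidy.redundancy_fit
#' @param object A `redundancy_fit`.
#' @export
autoplot.redundancy_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$activation)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::labs(x = "Gait cycle (%)", y = "Activation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Tidy a fiber-tuning fit
#'
#' @param x A `fiber_tuning_fit`.
#' @param ... Unused.
#' @return The per-muscle tuned parameter table (tuned and baseline values,
#'   tracking RMSE).
#' @export
tidy.fiber_tuning_fit <- function(x, ...) x$tuned

#' @rdname tidy.fiber_tuning_fit
#' @export
glance.fiber_tuning_fit <- function(x, ...) {
  tibble::tibble(
    n_tracked = length(x$tracked),
    aggregate_stiffness_n_mm = x$aggregate_stiffness_n_mm,
    constraint_active = x$constraint_active,
    mean_tracking_rmse = mean(x$tuned$tracking_rmse),
    converged = x$solver$converged
  )
}

#' @rdname tidy.fiber_tuning_fit
#' @param object A `fiber_tuning_fit`.
#' @export
autoplot.fiber_tuning_fit <- function(object, ...) {
  sol <- tidy(object$solution)
  sim <- sol[sol$muscle %in% object$tracked, c("pct", "muscle", "lm_tilde")]
  sim$what <- "simulated"
  ref <- object$refs
  names(ref)[names(ref) == "value"] <- "lm_tilde"
  ref$what <- "reference"
  d <- dplyr::bind_rows(sim, ref[, c("pct", "muscle", "lm_tilde", "what")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$lm_tilde,
                                  linetype = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::labs(x = "Gait cycle (%)", y = "Normalized fiber length",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a passive-tuning fit
#'
#' @param x A `passive_tuning_fit`.
#' @param ... Unused.
#' @return The per-group tuned passive parameters.
#' @export
tidy.passive_tuning_fit <- function(x, ...) x$groups

#' @rdname tidy.passive_tuning_fit
#' @export
glance.passive_tuning_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    n_trials = nrow(x$trials),
    objective = x$objective,
    min_r = min(x$trials$r, na.rm = TRUE),
    max_rmse = max(x$trials$rmse),
    converged = x$solver$converged
  )
}

#' @rdname tidy.passive_tuning_fit
#' @param object A `passive_tuning_fit`.
#' @param protocol The protocol the fit was computed from, for overlaying
#'   measured moments.
#' @export
autoplot.passive_tuning_fit <- function(object, protocol = NULL, ...) {
  if (is.null(protocol)) {
    stop("supply the protocol used for tuning to plot moment-angle fits",
         call. = FALSE)
  }
  d <- purrr::imap_dfr(protocol, function(tr, i) {
    pred <- predict_passive_moments(tr, object$params)$moment
    dplyr::bind_rows(
      tibble::tibble(trial = paste0("#", i, " ", tr$joint),
                     angle = tr$angles * 180 / pi, moment = tr$moment,
                     what = "measured"),
      tibble::tibble(trial = paste0("#", i, " ", tr$joint),
                     angle = tr$angles * 180 / pi, moment = pred,
                     what = "fitted")
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$angle, y = .data$moment,
                                  linetype = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trial, scales = "free") +
    ggplot2::labs(x = "Joint angle (deg)", y = "Passive moment (N m)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a metabolic trace
#'
#' @param x A `metabolic_trace`.
#' @param ... Unused.
#' @return Long tibble with columns `pct`, `muscle`, `rate_w`.
#' @export
tidy.metabolic_trace <- function(x, ...) {
  tibble::tibble(
    pct = rep(x$pct, length(x$muscles)),
    muscle = rep(x$muscles, each = length(x$pct)),
    rate_w = as.vector(x$rate)
  )
}

#' @rdname tidy.metabolic_trace
#' @export
glance.metabolic_trace <- function(x, ...) {
  avg <- whole_body_average(x$leg, x$met$body_mass, x$met$basal, x$time)
  tibble::tibble(
    net_w_kg = avg$net_w_kg,
    gross_w_kg = avg$gross_w_kg,
    peak_leg_w = max(x$leg),
    mean_leg_w = mean(x$leg)
  )
}

#' @rdname tidy.metabolic_trace
#' @param object A `metabolic_trace`.
#' @export
autoplot.metabolic_trace <- function(object, ...) {
  d <- tibble::tibble(pct = object$pct, leg = object$leg)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$leg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gait cycle (%)", y = "Leg metabolic rate (W)") +
    ggplot2::theme_minimal()
}
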