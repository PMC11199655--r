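#' Agreement metrics between two traces
#'
#' Pearson's linear correlation coefficient and root-mean-square error, the
#' two agreement measures used throughout the calibration diagnostics.
#' A constant `x` has no defined correlation; `r` is then `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A tibble with columns `r` and `rmse`.
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
fit_metrics <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  rmse <- sqrt(mean((x - y)^2))
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(x, y)
  }
  tibble::tibble(r = r, rmse = rmse)
}
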