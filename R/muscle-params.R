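# Muscle-tendon parameter tables: one row per muscle-tendon actuator.

.param_cols <- c("name", "F0", "lM0", "lTs", "theta0", "vmax", "kT",
                 "kPE", "s0", "sM", "slow_twitch_fraction", "group_id")

#' Build a muscle-tendon parameter table
#'
#' Returns a tibble with one row per muscle-tendon actuator and the columns
#' `name`, `F0` (maximum isometric force, N), `lM0` (optimal fiber length, m),
#' `lTs` (tendon slack length, m), `theta0` (pennation angle at optimal fiber
#' length, rad), `vmax` (maximum contraction velocity, optimal fiber lengths
#' per second), `kT` (normalized tendon stiffness), `kPE`, `s0`, `sM` (passive
#' force-length parameters), `slow_twitch_fraction`, and `group_id` (the
#' passive-parameter tying group). Missing optional columns are filled with
#' the package defaults; the table is validated before it is returned.
#'
#' @param x A data frame with at least `name`, `F0`, `lM0`, `lTs`.
#' @return A validated tibble of class `muscle_params`.
#' @examples
#' muscle_params(data.frame(name = "soleus", F0 = 1500, lM0 = 0.05, lTs = 0.3))
#' @export
muscle_params <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("name", "F0", "lM0", "lTs")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing muscle parameter columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(theta0 = 0, vmax = 10, kT = 35, kPE = 4, s0 = 1, sM = 0.6,
                   slow_twitch_fraction = 0.5, group_id = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  }
  if (all(is.na(x$group_id))) x$group_id <- x$name
  x <- x[, .param_cols]
  validate_muscle_params(x)
  class(x) <- c("muscle_params", class(x))
  x
}

validate_muscle_params <- function(x) {
  with(x, {
    stopifnot(
      !anyDuplicated(name),
      all(F0 > 0), all(lM0 > 0), all(lTs > 0), all(vmax > 0),
      all(kT > 0), all(kPE > 0), all(sM > 0),
      all(theta0 >= 0), all(theta0 < pi / 2),
      all(slow_twitch_fraction >= 0), all(slow_twitch_fraction <= 1)
    )
  })
  invisible(x)
}

#' Default passive force-length parameters
#'
#' The generic passive curve parameters `(kPE, s0, sM) = (4, 1, 0.6)` used as
#' defaults and as the regularization anchor of the passive tuning stage.
#'
#' @return Named numeric vector with elements `kPE`, `s0`, `sM`.
#' @export
default_passive_params <- function() {
  c(kPE = 4, s0 = 1, sM = 0.6)
}

#' Bounds of the passive-parameter tuning boxes
#'
#' Box bounds derived from the defaults: `kPE` and `s0` within +/-25% and `sM`
#' within +/-33% of their default values.
#'
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
passive_param_bounds <- function() {
  def <- default_passive_params()
  frac <- c(kPE = 0.25, s0 = 0.25, sM = 0.33)
  tibble::tibble(
    param = names(def),
    lower = unname(def * (1 - frac)),
    upper = unname(def * (1 + frac))
  )
}

#' Read and write muscle parameter files
#'
#' Muscle parameters are serialized as a mapping keyed by muscle name, each
#' entry holding the fields of the parameter table. JSON (`.json`) and YAML
#' (`.yml`/`.yaml`) are supported, chosen by file extension.
#'
#' @param muscles A [muscle_params()] table.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `read_muscle_params()` returns a `muscle_params` tibble;
#'   `write_muscle_params()` returns `path` invisibly.
#' @export
write_muscle_params <- function(muscles, path) {
  muscles <- muscle_params(muscles)
  entries <- lapply(seq_len(nrow(muscles)), function(i) {
    row <- as.list(muscles[i, setdiff(.param_cols, "name")])
    row
  })
  names(entries) <- muscles$name
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(entries, path, precision = 15)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_muscle_params
#' @export
read_muscle_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  entries <- if (ext == "json") {
    jsonlite::read_json(path)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  }
  rows <- purrr::imap(entries, function(e, nm) {
    e$group_id <- e$group_id %||% NA_character_
    tibble::as_tibble(c(list(name = nm), e))
  })
  muscle_params(dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
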