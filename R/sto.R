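# OpenSim storage (.sto/.mot) text dialect: a free-form header terminated by
# the literal line "endheader", a tab-separated column-name row whose first
# column is "time", and one whitespace-separated data row per time point.

#' Read an OpenSim storage file
#'
#' Parses the `.sto`/`.mot` text dialect. Header fields `nRows`, `nColumns`
#' and `inDegrees` are honored: row/column counts are checked against the data
#' and, when `inDegrees=yes`, joint-angle columns (prefix `q_`) are converted
#' to radians on load. Time must be strictly increasing.
#'
#' @param path Path to the storage file.
#' @return A tibble with one column per storage column.
#' @export
read_storage <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stop("malformed storage file: no `endheader` line",
                       call. = FALSE)
  header <- lines[seq_len(end - 1)]
  meta <- list()
  for (h in header) {
    if (grepl("=", h, fixed = TRUE)) {
      kv <- strsplit(h, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  cols <- strsplit(trimws(body[1]), "[\t ]+")[[1]]
  rows <- strsplit(trimws(body[-1]), "[\t ]+")
  nfield <- lengths(rows)
  if (length(unique(nfield)) > 1 || (length(nfield) && nfield[1] != length(cols))) {
    stop("ragged rows in storage file", call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric data in storage file", call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- cols
  if (!is.null(meta$nRows) && as.integer(meta$nRows) != nrow(out)) {
    stop("header nRows does not match data", call. = FALSE)
  }
  if (!is.null(meta$nColumns) && as.integer(meta$nColumns) != ncol(out)) {
    stop("header nColumns does not match data", call. = FALSE)
  }
  if (identical(names(out)[1], "time") && any(diff(out$time) <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  if (tolower(meta$inDegrees %||% "no") == "yes") {
    ang <- grep("^q_", names(out))
    out[ang] <- out[ang] * pi / 180
  }
  out
}

#' Write an OpenSim storage file
#'
#' Writes a table in the `.sto` text dialect with a minimal header
#' (`version`, `nRows`, `nColumns`, `inDegrees=no`). Values are written with
#' 15 significant digits so a read/write round trip is exact to well below
#' 1e-10.
#'
#' @param table A data frame whose first column is `time`.
#' @param path Output file path.
#' @param name Name recorded on the first header line.
#' @return `path`, invisibly.
#' @export
write_storage <- function(table, path, name = "gaittune") {
  table <- as.data.frame(table)
  header <- c(
    name,
    "version=1",
    paste0("nRows=", nrow(table)),
    paste0("nColumns=", ncol(table)),
    "inDegrees=no",
    "endheader"
  )
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  rows <- apply(table, 1, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(c(header, paste(names(table), collapse = "\t"), rows), path)
  invisible(path)
}
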