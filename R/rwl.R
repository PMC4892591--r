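#' Read a Tucson-format ring-width file
#'
#' Parses a decadal Tucson (ITRDB) `.rwl` file into a list of ring-width
#' series. Values are assumed to be in units of 0.01 mm and are converted to
#' mm. Both series terminators in common use (`999` and `-9999`) are
#' accepted; the dialect seen for each series is recorded in the result.
#' Up to three leading header lines (lines whose year field is not an
#' integer) are skipped.
#'
#' @param path path to a `.rwl` file.
#' @param site_id site identifier attached to every series; defaults to the
#'   file name without extension.
#' @return a named list of `ring_series` objects (fields `core_id`,
#'   `site_id`, `first_year`, `widths` in mm), one per core.
#' @export
read_rwl <- function(path, site_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  site_id <- site_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  dialects <- character()
  open_id <- NULL; open_first <- NA_integer_; open_vals <- numeric()
  header_budget <- 3L
  seen_data <- FALSE
  close_series <- function() {
    if (is.null(open_id)) return(invisible())
    if (open_id %in% names(series))
      stop("duplicate core id '", open_id, "' in ", path, call. = FALSE)
    series[[open_id]] <<- ring_series(open_id, site_id, open_first, open_vals)
    open_id <<- NULL; open_vals <<- numeric()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1L, 8L))
    rest <- strsplit(trimws(substring(ln, 9L)), "\\s+")[[1]]
    yr <- suppressWarnings(as.integer(rest[1L]))
    if (is.na(yr)) {
      if (header_budget > 0L && !seen_data) { header_budget <- header_budget - 1L; next }
      stop(sprintf("malformed decade line %d in %s", i, path), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(rest[-1L]))
    if (anyNA(vals))
      stop(sprintf("malformed decade line %d in %s", i, path), call. = FALSE)
    seen_data <- TRUE
    if (!identical(id, open_id)) { close_series(); open_id <- id; open_first <- yr }
    term <- which(vals == 999 | vals == -9999)
    if (length(term)) {
      dialects[id] <- if (vals[term[1L]] == 999) "999" else "-9999"
      vals <- vals[seq_len(term[1L] - 1L)]
      open_vals <- c(open_vals, vals / 100)
      close_series()
    } else {
      open_vals <- c(open_vals, vals / 100)
    }
  }
  close_series()
  if (!length(series)) stop("no ring-width series found in ", path, call. = FALSE)
  attr(series, "terminators") <- dialects
  series
}

#' Write ring-width series to a Tucson-format file
#'
#' Writes a list of [ring_series()] objects as a decadal Tucson `.rwl`
#' file with values in 0.01 mm and the `999` terminator.
#'
#' @param series a list of `ring_series` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rwl <- function(series, path) {
  if (!length(series)) stop("no series to write", call. = FALSE)
  out <- character()
  for (s in series) {
    vals <- as.integer(round(s$widths * 100))
    yrs <- series_years(s)
    id <- substr(s$core_id, 1L, 8L)
    i <- 1L
    n <- length(vals)
    while (i <= n) {
      y0 <- yrs[i]
      dec_end <- (y0 %/% 10L) * 10L + 9L
      j <- min(n, i + (dec_end - y0))
      fields <- sprintf("%6d", vals[i:j])
      if (j == n) fields <- c(fields, if (yrs[j] < dec_end) sprintf("%6d", 999L) else NULL)
      out <- c(out, paste0(sprintf("%-8s%4d", id, y0), paste(fields, collapse = "")))
      if (j == n && yrs[j] == dec_end)
        out <- c(out, paste0(sprintf("%-8s%4d", id, yrs[j] + 1L), sprintf("%6d", 999L)))
      i <- j + 1L
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a ring-width series
#'
#' One core's contiguous annual ring widths anchored at a first calendar
#' year.
#'
#' @param core_id core identifier (at most 8 characters survive `.rwl`
#'   round trips).
#' @param site_id site identifier.
#' @param first_year calendar year of the first width.
#' @param widths positive ring widths in mm.
#' @return an object of class `ring_series`.
#' @export
ring_series <- function(core_id, site_id, first_year, widths) {
  if (!length(widths)) stop("widths must be non-empty", call. = FALSE)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("widths must be finite and > 0", call. = FALSE)
  structure(list(core_id = as.character(core_id), site_id = as.character(site_id),
                 first_year = as.integer(first_year), widths = as.numeric(widths)),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("ring_series %s (site %s): %d years %d-%d, mean width %.2f mm\n",
              x$core_id, x$site_id, length(x$widths), min(yrs), max(yrs),
              mean(x$widths)))
  invisible(x)
}
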