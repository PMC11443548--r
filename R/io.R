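#' Write and read gridded fields as portable text
#'
#' Gridded variables are serialized as a long-format CSV (columns `time`,
#' `lat`, `lon`, `variable`, `value`, ISO-8601 dates, empty cells for masked
#' data) plus a JSON metadata sidecar (`<path>.json`) recording units per
#' variable, in the spirit of CF attribute conventions. One file may hold
#' several co-registered variables. The round trip is lossless to
#' floating-point representation.
#'
#' @param field A [geo_field()] or a list of co-registered `geo_field`s.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path) {
  if (inherits(field, "geo_field")) field <- list(field)
  stopifnot(all(vapply(field, inherits, logical(1), "geo_field")))
  g0 <- field[[1]]$grid
  rows <- do.call(rbind, lapply(field, function(f) {
    if (!isTRUE(all.equal(f$grid$lats, g0$lats)) ||
        !isTRUE(all.equal(f$grid$lons, g0$lons))) {
      stop("all variables in one file must share a grid")
    }
    nd <- dim(f$values)
    data.frame(
      time = rep(as.character(f$times), times = nd[2] * nd[3]),
      lat = rep(rep(f$grid$lats, each = nd[1]), times = nd[3]),
      lon = rep(f$grid$lons, each = nd[1] * nd[2]),
      variable = f$var,
      # %.17g preserves doubles exactly across the text round trip
      value = ifelse(is.na(as.vector(f$values)), "",
                     sprintf("%.17g", as.vector(f$values))),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "", quote = FALSE)
  meta <- list(
    conventions = "seabloom-text-1",
    variables = stats::setNames(
      lapply(field, function(f) list(units = f$units)),
      vapply(field, function(f) f$var, character(1))
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read one gridded variable from a portable text file
#'
#' Reconstructs a [geo_field()] from a file written by [write_field()]. Axes
#' are normalized to `(time, ascending lat, ascending lon)` regardless of row
#' order on disk; empty cells become the missing-data mask; units are taken
#' from the JSON sidecar when present.
#'
#' @param path CSV path.
#' @param var Variable name to extract.
#' @return A [geo_field()].
#' @export
read_field <- function(path, var) {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "variable", "value")
  if (!all(need %in% names(rows))) {
    stop("not a gridded-field file (expected columns: ", paste(need, collapse = ", "), ")")
  }
  have <- unique(rows$variable)
  if (!var %in% have) {
    stop("variable '", var, "' not found; available: ", paste(have, collapse = ", "))
  }
  rows <- rows[rows$variable == var, ]
  times <- sort(unique(as.Date(rows$time)))
  lats <- sort(unique(rows$lat))
  lons <- sort(unique(rows$lon))
  grid <- geo_grid(lats, lons)
  vals <- array(NA_real_, dim = c(length(times), length(lats), length(lons)))
  it <- match(as.Date(rows$time), times)
  ila <- match(rows$lat, lats)
  ilo <- match(rows$lon, lons)
  vals[cbind(it, ila, ilo)] <- rows$value
  units <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    u <- meta$variables[[var]]$units
    if (!is.null(u)) units <- u
  }
  geo_field(vals, grid, times, units = units, var = var)
}

#' Write / read a point time series as CSV
#'
#' ISO-8601 dates, empty cells for missing values, units in a `# units:`
#' comment header.
#'
#' @param series A [geo_series()].
#' @param path CSV path.
#' @return `path` (write) or a [geo_series()] (read).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "geo_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", attr(series, "units")), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  units <- if (startsWith(first, "# units:")) trimws(sub("^# units:", "", first)) else ""
  rows <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  geo_series(as.Date(rows$time), rows$value, units = units)
}

#' Write / read a vertical profile as CSV
#'
#' Columns `depth` (m, positive down) or `pressure` (dbar), `temperature`
#' (degC) and `qc` (integer flags, 1 = good); float identifier and time in
#' comment headers.
#'
#' @param profile A profile object (see [make_profile()]).
#' @param path CSV path.
#' @return `path` (write) or a profile (read).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# float_id: ", attr(profile, "float_id")),
               paste0("# time: ", as.character(attr(profile, "time")))), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 2)
  rows <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  vert <- if ("depth" %in% names(rows)) "depth" else "pressure"
  new_profile(rows,
              float_id = trimws(sub("^# float_id:", "", hdr[1])),
              time = as.Date(trimws(sub("^# time:", "", hdr[2]))),
              vertical = vert)
}

#' Serialize ground-truth objects as JSON sidecars
#'
#' Synthetic-data generators return truth objects sufficient to score the
#' recovery of the corresponding analysis stage; these helpers persist them
#' next to the generated data files.
#'
#' @param truth Any truth object (plain list / data.frame structure).
#' @param path JSON path.
#' @return `path` (write) or the parsed structure (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
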