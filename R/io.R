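#' Read a long-format activity table from CSV
#'
#' Expects columns `site`, `station`, `species`, `period`, `count` with
#' non-negative integer counts and a unique (site, station, species, period)
#' key.
#'
#' @param path CSV file path.
#' @return Validated activity `data.frame`.
#' @export
read_activity <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "station", "species", "period", "count")
  if (!all(need %in% names(tab)))
    stop("activity table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(tab$count < 0, na.rm = TRUE) ||
      any(tab$count != round(tab$count), na.rm = TRUE))
    stop("counts must be non-negative integers", call. = FALSE)
  key <- paste(tab$site, tab$station, tab$species, tab$period)
  if (anyDuplicated(key))
    stop("duplicate (site, station, species, period) keys", call. = FALSE)
  tab
}

#' Read a site metadata table from CSV
#'
#' Expects `site`, projected `x`/`y` coordinates and the seven land-cover
#' proportion columns.
#'
#' @param path CSV file path.
#' @return Validated metadata `data.frame`.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "x", "y", land_classes)
  if (!all(need %in% names(meta)))
    stop("site metadata must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  meta
}

#' Read a species status table from CSV
#'
#' Expects `species` and `status` (`native` / `alien` / `uncertain`).
#'
#' @param path CSV file path.
#' @return Validated status `data.frame`.
#' @export
read_status <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "status") %in% names(st)))
    stop("status table must have columns species, status", call. = FALSE)
  bad <- setdiff(unique(st$status), c("native", "alien", "uncertain"))
  if (length(bad))
    stop("unknown status values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  st
}

#' Read a per-site temperature series from CSV
#'
#' Expects `site`, `period` and at least one of `air_temp`, `soil_temp`.
#' The series can be decomposed with [fit_tslm()] exactly like an activity
#' series, e.g. to compare the absolute seasonal variance of temperature
#' with the land-cover gradient.
#'
#' @param path CSV file path.
#' @return Validated temperature `data.frame`.
#' @export
read_temperature <- function(path) {
  tp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "period") %in% names(tp)) ||
      !any(c("air_temp", "soil_temp") %in% names(tp)))
    stop("temperature table must have columns site, period and ",
         "air_temp and/or soil_temp", call. = FALSE)
  tp
}

#' Read a flat key: value configuration file
#'
#' @param path Text file of `key: value` lines (as written by
#'   [write_config()]).
#' @return Named character vector of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  stats::setNames(vapply(kv, `[[`, "", 3),
                  trimws(vapply(kv, `[[`, "", 2)))
}
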