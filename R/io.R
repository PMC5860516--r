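# Plain-text readers and writers for panels, locations and temperature.
# All files are comma-delimited UTF-8 with a header line and "." as the
# decimal separator.

#' Write a panel (and optional ground truth) to a directory
#'
#' Writes `panel.csv` (one practice-month record per row) and
#' `locations.csv`; when given a full simulation, also writes the
#' daily temperature as `daily_temperature.csv` and the ground truth as
#' a structured JSON sidecar `truth.json`.
#'
#' @param x a `practice_panel` or a `panel_sim` from [gen_panel].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_panel <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "panel_sim")) {
    panel <- x$panel
    write.csv(x$daily_temp, file.path(dir, "daily_temperature.csv"),
              row.names = FALSE)
    truth <- x$truth
    truth$cfg <- unclass(truth$cfg)
    truth$cfg$anchor <- format(truth$cfg$anchor)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else panel <- x
  stopifnot(inherits(panel, "practice_panel"))
  write.csv(panel$records, file.path(dir, "panel.csv"), row.names = FALSE)
  write.csv(panel$locations, file.path(dir, "locations.csv"),
            row.names = FALSE)
  invisible(file.path(dir, c("panel.csv", "locations.csv")))
}

#' Read a practice panel from delimited text
#'
#' @param panel_path path to the records file (columns `practice_id`,
#'   `month` or ISO-8601 `date`, `log_rate`, covariates).
#' @param locations_path path to the locations file (`practice_id`,
#'   `easting`, `northing`).
#' @param anchor first day of month 1; used to convert a `date` column
#'   to month indices when no `month` column is present.
#' @return a validated `practice_panel`; row count and missingness are
#'   reported via `message`.
#' @export
read_panel <- function(panel_path, locations_path,
                       anchor = as.Date("2002-01-01")) {
  records <- read.csv(panel_path, stringsAsFactors = FALSE)
  locations <- read.csv(locations_path, stringsAsFactors = FALSE)
  anchor <- as.Date(anchor)
  if (!"month" %in% names(records) && "date" %in% names(records)) {
    d <- as.Date(records$date)
    records$month <- 12L * (as.integer(format(d, "%Y")) -
                            as.integer(format(anchor, "%Y"))) +
      (as.integer(format(d, "%m")) - as.integer(format(anchor, "%m"))) + 1L
    records$date <- NULL
  }
  panel <- as_practice_panel(records, locations, anchor = anchor)
  message(sprintf("read %d records (%d practices, %d missing log_rate)",
                  nrow(panel$records),
                  length(unique(panel$records$practice_id)),
                  sum(is.na(panel$records$log_rate))))
  panel
}

#' Read a daily temperature series
#'
#' @param path delimited text with columns `date` (ISO-8601) and
#'   `temp_c`.
#' @return data frame with `date` (Date) and `temp_c`.
#' @export
read_daily_temperature <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "temp_c") %in% names(x)))
    stop("missing column(s): need `date` and `temp_c`")
  x$date <- as.Date(x$date)
  if (any(is.na(x$date))) stop("unparseable dates in ", path)
  x[order(x$date), , drop = FALSE]
}
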