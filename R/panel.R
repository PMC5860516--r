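# The practice-panel container: long-format records plus locations.

#' Assemble and validate a practice panel
#'
#' A practice panel holds long-format practice-month records (one row
#' per practice and month, with the log outcome rate and covariates)
#' together with projected planar coordinates for every practice.
#' Months are integer indices 1..T; gaps within a practice are permitted
#' and flagged, but every record must have a location and months must be
#' non-decreasing within practice.
#'
#' @param records data frame with at least `practice_id`, `month`
#'   (integer) and `log_rate`; any further numeric columns are treated
#'   as covariates.
#' @param locations data frame with `practice_id`, `easting`,
#'   `northing` (metres, projected planar coordinates).
#' @param anchor first day of month 1.
#' @return an object of class `practice_panel`: a list with elements
#'   `records`, `locations`, `covariates` (names) and `anchor`.
#' @export
as_practice_panel <- function(records, locations,
                              anchor = as.Date("2002-01-01")) {
  req <- c("practice_id", "month", "log_rate")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s) in records: ", paste(miss, collapse = ", "))
  loc_req <- c("practice_id", "easting", "northing")
  miss <- setdiff(loc_req, names(locations))
  if (length(miss))
    stop("missing column(s) in locations: ", paste(miss, collapse = ", "))
  records$practice_id <- as.character(records$practice_id)
  locations$practice_id <- as.character(locations$practice_id)
  if (anyDuplicated(locations$practice_id))
    stop("duplicated practice_id in locations")
  orphan <- setdiff(unique(records$practice_id), locations$practice_id)
  if (length(orphan))
    stop("practice(s) without a location: ", paste(orphan, collapse = ", "))
  records$month <- as.integer(records$month)
  if (any(is.na(records$month)) || any(records$month < 1L))
    stop("`month` must be positive integers")
  bad <- vapply(split(records$month, records$practice_id),
                function(m) is.unsorted(m, strictly = TRUE), logical(1))
  if (any(bad))
    stop("months not strictly increasing within practice(s): ",
         paste(names(bad)[bad], collapse = ", "))
  covariates <- setdiff(names(records), req)
  n_p <- length(unique(records$practice_id))
  n_t <- max(records$month)
  complete <- nrow(records) == n_p * n_t
  structure(list(records = records,
                 locations = locations[, loc_req],
                 covariates = covariates,
                 anchor = as.Date(anchor),
                 complete = complete),
            class = "practice_panel")
}

#' @export
print.practice_panel <- function(x, ...) {
  cat(sprintf(
    "Practice panel: %d records, %d practices, months 1..%d%s\n",
    nrow(x$records), length(unique(x$records$practice_id)),
    max(x$records$month),
    if (x$complete) "" else " (incomplete: some practice-months absent)"))
  cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Area-wide monthly average of the panel outcome
#'
#' The cross-practice mean of the log outcome rate per month, the series
#' to which the stage-one seasonal model is fitted.
#'
#' @param panel a `practice_panel`.
#' @return a [monthly_series].
#' @export
area_average <- function(panel) {
  stopifnot(inherits(panel, "practice_panel"))
  months <- seq_len(max(panel$records$month))
  m <- tapply(panel$records$log_rate, panel$records$month,
              mean, na.rm = TRUE)
  vals <- rep(NA_real_, length(months))
  vals[as.integer(names(m))] <- as.numeric(m)
  monthly_series(months, vals, anchor = panel$anchor)
}
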