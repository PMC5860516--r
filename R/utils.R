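# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state so that seeded
#' simulation helpers do not disturb the caller's stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one user seed into named substreams, all < 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(generator = 11L, temperature = 211L, locations = 307L,
               optimizer = 401L, permutation = 503L, pipeline = 601L)
  if (!stream %in% names(offsets))
    stop("unknown substream: ", stream)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

#' Monthly series container
#'
#' A regularly spaced monthly series: integer month index 1..T (unit
#' spacing enforced) and one value per month, `NA` marking missing
#' months.  Used both for area-wide log outcome rates and for
#' monthly-averaged temperature.
#'
#' @param month integer vector of month indices, strictly increasing and
#'   unit spaced.
#' @param value numeric vector, same length as `month`; `NA` allowed.
#' @param anchor `Date` (or string) giving the first day of month 1;
#'   used when pairing with daily series.
#' @return an object of class `monthly_series` (a data frame with columns
#'   `month` and `value`, plus an `anchor` attribute).
#' @examples
#' monthly_series(1:12, sin(2 * pi * (1:12) / 12))
#' @export
monthly_series <- function(month, value, anchor = as.Date("2002-01-01")) {
  month <- as.integer(month)
  value <- as.numeric(value)
  if (length(month) != length(value))
    stop("`month` and `value` must have the same length")
  if (length(month) < 1L) stop("empty series")
  if (any(diff(month) != 1L))
    stop("`month` must be strictly increasing with unit spacing")
  if (all(is.na(value))) stop("series has no non-missing value")
  out <- data.frame(month = month, value = value)
  attr(out, "anchor") <- as.Date(anchor)
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' @export
print.monthly_series <- function(x, ...) {
  cat("Monthly series: months", min(x$month), "..", max(x$month),
      sprintf("(%d missing), anchor %s\n", sum(is.na(x$value)),
              format(attr(x, "anchor"))))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# First days of n consecutive calendar months starting at `anchor`
# (which must itself be a first-of-month), plus the last day of each.
month_spans <- function(anchor, n_months) {
  anchor <- as.Date(anchor)
  if (as.integer(format(anchor, "%d")) != 1L)
    stop("anchor date must be the first day of a month")
  starts <- seq(anchor, by = "month", length.out = n_months + 1L)
  data.frame(month = seq_len(n_months),
             start = starts[-(n_months + 1L)],
             end = starts[-1L] - 1L)
}

# Squared Pearson correlation between observed and fitted values.

#' Goodness of fit as squared correlation
#'
#' The fit statistic used to compare seasonal models: the squared Pearson
#' correlation between observed and fitted values over months where both
#' are available.
#'
#' @param observed,fitted numeric vectors of equal length; `NA`s are
#'   dropped pairwise.
#' @return a single number in \[0, 1\].
#' @export
goodness_of_fit <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("`observed` and `fitted` must have the same length")
  ok <- !is.na(observed) & !is.na(fitted)
  if (sum(ok) < 3L) stop("need at least 3 non-missing pairs")
  if (sd(observed[ok]) == 0 || sd(fitted[ok]) == 0)
    stop("undefined statistic: zero variance in observed or fitted values")
  cor(observed[ok], fitted[ok])^2
}
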