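# Daily temperature: synthetic generation and lagged monthly averaging.

#' Generate a synthetic daily temperature series
#'
#' Produces one temperature value per calendar day covering `n_months`
#' consecutive months from `anchor`, as an annual sinusoid (coldest in
#' mid-winter) plus independent daily noise.  Defaults approximate a
#' cool-temperate maritime climate (annual mean about 9.5 degrees C,
#' seasonal amplitude 6.5, coldest around late January).  `pad_days`
#' extra days before the anchor are included so that lagged monthly
#' averages near the start of the study window remain computable.
#'
#' @param n_months number of calendar months to cover (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the series.
#' @param anchor first day of month 1 (first of a calendar month).
#' @param mean_c annual mean temperature, degrees C.
#' @param amplitude_c half-range of the annual cycle, degrees C.
#' @param coldest_doy day of year at which the sinusoid attains its
#'   minimum (default 25, late January).
#' @param noise_sd standard deviation of iid daily noise, degrees C.
#' @param pad_days days generated before `anchor` (default 31, enough
#'   for a one-month lag).
#' @return data frame with columns `date` and `temp_c`.
#' @examples
#' tmp <- gen_temperature(12, seed = 1, noise_sd = 0)
#' range(tmp$temp_c)
#' @export
gen_temperature <- function(n_months, seed = NULL,
                            anchor = as.Date("2002-01-01"),
                            mean_c = 9.5, amplitude_c = 6.5,
                            coldest_doy = 25, noise_sd = 2,
                            pad_days = 31L) {
  if (!is.numeric(n_months) || length(n_months) != 1L || n_months < 1)
    stop("invalid argument: `n_months` must be a positive count")
  if (noise_sd < 0) stop("invalid argument: `noise_sd` must be >= 0")
  spans <- month_spans(anchor, n_months)
  dates <- seq(spans$start[1L] - pad_days, spans$end[n_months], by = "day")
  doy <- as.numeric(format(dates, "%j"))
  mu <- mean_c - amplitude_c * cos(2 * pi * (doy - coldest_doy) / 365.25)
  noise <- with_seed(seed, rnorm(length(dates), sd = noise_sd))
  data.frame(date = dates, temp_c = mu + noise)
}

# Map a lag choice ("0d","7d","14d","21d","1m" or a day count) to days;
# "1m" is handled specially (previous calendar month) and coded as NA here.
lag_days <- function(lag) {
  if (is.numeric(lag)) {
    if (lag < 0) stop("invalid argument: negative lag")
    return(as.integer(lag))
  }
  switch(as.character(lag),
         "0d" = 0L, "7d" = 7L, "14d" = 14L, "21d" = 21L, "1m" = NA_integer_,
         stop("unknown lag choice: ", lag,
              " (use '0d', '7d', '14d', '21d', '1m', or a day count)"))
}

# Nominal ordering value for tie-breaks: "1m" counts as 31 days.
lag_order_days <- function(lag) {
  d <- lag_days(lag)
  if (is.na(d)) 31L else d
}

#' Monthly means of a lagged daily temperature series
#'
#' For each study month t the returned value is the mean of the daily
#' series over the calendar span of month t shifted back by `lag` days,
#' i.e. the 28--31 days ending `lag` days before the corresponding days
#' of month t.  The special choice `"1m"` uses the mean of the previous
#' calendar month.  Months whose shifted span is not fully covered by
#' the daily series are returned as `NA` with a warning, never silently
#' imputed or truncated.
#'
#' @param daily_temp data frame with columns `date` (Date) and `temp_c`.
#' @param lag one of `"0d"`, `"7d"`, `"14d"`, `"21d"`, `"1m"`, or a
#'   nonnegative day count.
#' @param n_months number of study months.
#' @param anchor first day of study month 1.
#' @return a [monthly_series] of lagged monthly mean temperatures.
#' @examples
#' tmp <- gen_temperature(14, seed = 2)
#' lag_temperature(tmp, "7d", n_months = 14)
#' @export
lag_temperature <- function(daily_temp, lag = "0d", n_months,
                            anchor = as.Date("2002-01-01")) {
  if (!all(c("date", "temp_c") %in% names(daily_temp)))
    stop("`daily_temp` must have columns `date` and `temp_c`")
  dates <- as.Date(daily_temp$date)
  if (anyDuplicated(dates)) stop("duplicated dates in daily series")
  spans <- month_spans(anchor, n_months)
  d <- lag_days(lag)
  vals <- rep(NA_real_, n_months)
  for (t in seq_len(n_months)) {
    if (is.na(d)) {                      # "1m": previous calendar month
      lo <- seq(spans$start[t], by = "-1 month", length.out = 2L)[2L]
      hi <- spans$start[t] - 1L
    } else {
      lo <- spans$start[t] - d
      hi <- spans$end[t] - d
    }
    need <- seq(lo, hi, by = "day")
    idx <- match(need, dates)
    if (anyNA(idx) || anyNA(daily_temp$temp_c[idx])) next
    vals[t] <- mean(daily_temp$temp_c[idx])
  }
  if (anyNA(vals))
    warning(sprintf(
      "daily series does not cover the lagged span of %d month(s); %s",
      sum(is.na(vals)), "returned as missing"))
  monthly_series(seq_len(n_months), vals, anchor = anchor)
}
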