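# Maximum-likelihood fitting of the DHR, the static harmonic
# comparator, temperature-lag selection, and the seasonal-partition
# (temperature anomaly) identity.

#' Fit a dynamic harmonic regression by maximum likelihood
#'
#' Maximises the prediction-error log-likelihood from [kalman_loglik]
#' over the log-variances (unconstrained scale) with a set of
#' deterministic quasi-Newton starts, then smooths to obtain the fitted
#' seasonal curve.  The hyperparameters are the random-walk innovation
#' variance of each harmonic pair and the observation variance.
#'
#' @param y numeric vector or [monthly_series] of the area-wide monthly
#'   log outcome rate.
#' @param temperature a [monthly_series] of lagged monthly mean
#'   temperatures (ignored when the spec excludes temperature).
#' @param spec a [dhr_spec].
#' @param n_starts number of deterministic multi-starts (default 5).
#' @param reltol relative convergence tolerance of the optimiser.
#' @return an object of class `dhr_fit`: estimated hyperparameters
#'   (`rw_var` per harmonic, `obs_var`), smoothed state paths,
#'   `fitted` values \eqn{\hat\mu_t}, `loglik`, `r2` (squared
#'   correlation of observed and fitted), innovations, and convergence
#'   information.  If no start converges the best-found parameters are
#'   still attached and `converged` is `FALSE`.
#' @examples
#' sim <- gen_panel(panel_gen_config(n_practices = 4, n_months = 36,
#'                                   seed = 3))
#' dlag <- lag_temperature(sim$daily_temp, "7d", n_months = 36)
#' fit <- fit_dhr(sim$area_series, dlag, dhr_spec(k = 2))
#' fit$r2
#' @export
fit_dhr <- function(y, temperature = NULL, spec = dhr_spec(),
                    n_starts = 5L, reltol = 1e-8) {
  yv <- if (inherits(y, "monthly_series")) y$value else as.numeric(y)
  Tn <- length(yv)
  nh <- n_hyper(spec)
  dim_state <- 1L + spec$include_temperature + spec$trend + 2L * spec$k
  n_ok <- if (spec$include_temperature)
    sum(!is.na(yv) & !is.na(temperature$value)) else sum(!is.na(yv))
  if (n_ok < dim_state + 2L)
    stop("too few overlapping non-missing months (need state dim + 2)")

  mk_ss <- function(theta) {
    vars <- exp(theta)
    build_state_space(spec, temperature,
                      hyper = list(rw_var = vars[-nh], obs_var = vars[nh]),
                      n_months = Tn)
  }
  negll <- function(theta) {
    val <- tryCatch(-kalman_loglik(mk_ss(theta), yv)$loglik,
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  # Deterministic starts anchored at the static-fit residual variance:
  # random-walk variance as a sliding fraction of it.
  v0 <- tryCatch({
    st <- fit_static_harmonic(yv, temperature, k = spec$k,
                              include_temperature = spec$include_temperature,
                              trend = spec$trend)
    max(st$sigma2, 1e-8)
  }, error = function(e) max(var(yv, na.rm = TRUE), 1e-8))
  fracs <- c(1e-2, 1e-4, 1e-1, 1e-6, 1)[seq_len(max(1L, n_starts))]
  best <- NULL
  evals <- list()
  for (f in fracs) {
    theta0 <- log(c(rep(f * v0, nh - 1L), v0))
    opt <- tryCatch(
      optim(theta0, negll, method = "BFGS",
            control = list(reltol = reltol, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    evals[[length(evals) + 1L]] <- opt
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("DHR fit failed: no optimiser start succeeded")
  converged <- any(vapply(evals, function(o)
    o$convergence == 0L && o$value <= best$value + 1e-6, logical(1)))

  ss <- mk_ss(best$par)
  kf <- kalman_loglik(ss, yv)
  sm <- kalman_smooth(ss, yv, kf)
  vars <- exp(best$par)
  rw_var <- rep_len(vars[-nh], spec$k)
  fit <- list(spec = spec,
              rw_var = setNames(rw_var, paste0("harmonic", seq_len(spec$k))),
              obs_var = vars[nh],
              loglik = -best$value,
              states = sm$states, state_var = sm$state_var,
              fitted = sm$fitted, fitted_var = sm$fitted_var,
              innovations = kf$v, innovation_var = kf$F,
              r2 = goodness_of_fit(yv, sm$fitted),
              converged = converged, n_starts = length(evals),
              y = yv, temperature = temperature)
  class(fit) <- "dhr_fit"
  if (!converged)
    warning("DHR optimiser did not report convergence; ",
            "best-found parameters returned")
  fit
}

#' @export
print.dhr_fit <- function(x, ...) {
  cat(sprintf(
    "Dynamic harmonic regression: k = %d, %s temperature (lag %s)\n",
    x$spec$k, if (x$spec$include_temperature) "with" else "without",
    x$spec$lag))
  cat(sprintf("  log-likelihood %.3f, R^2 = %.3f%s\n", x$loglik, x$r2,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  RW innovation variances:",
      paste(signif(x$rw_var, 3), collapse = ", "),
      "; obs variance:", signif(x$obs_var, 3), "\n")
  invisible(x)
}

#' Fit a static harmonic regression by ordinary least squares
#'
#' The time-invariant counterpart of the DHR: OLS of the series on an
#' intercept, the (lagged) temperature, and `k` harmonic cosine/sine
#' pairs at multiples of `2*pi/12`.
#'
#' @inheritParams fit_dhr
#' @param k number of harmonics (0 allowed: no seasonal terms).
#' @param include_temperature include the temperature regressor?
#' @param trend include a linear time trend?
#' @return an object of class `static_harmonic_fit`: `coef`, `fitted`
#'   (NA where a regressor is missing), `residuals`, `r2`, `sigma2`.
#' @export
fit_static_harmonic <- function(y, temperature = NULL, k = 2L,
                                include_temperature = TRUE,
                                trend = FALSE) {
  yv <- if (inherits(y, "monthly_series")) y$value else as.numeric(y)
  Tn <- length(yv)
  t <- seq_len(Tn)
  X <- matrix(1, Tn, 1L, dimnames = list(NULL, "a"))
  if (include_temperature) {
    if (is.null(temperature)) stop("temperature series required")
    d <- if (inherits(temperature, "monthly_series"))
      temperature$value else as.numeric(temperature)
    if (length(d) != Tn) stop("temperature length != series length")
    X <- cbind(X, beta = d)
  }
  if (trend) X <- cbind(X, trend = t)
  if (k > 0) for (p in seq_len(k)) {
    X <- cbind(X, cos(p * 2 * pi * t / 12), sin(p * 2 * pi * t / 12))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("A", "B"), p)
  }
  ok <- !is.na(yv) & stats::complete.cases(X)
  if (sum(ok) < ncol(X)) stop("too few complete observations for OLS")
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, yv[ok])
  fitted <- rep(NA_real_, Tn)
  fitted[stats::complete.cases(X)] <-
    drop(X[stats::complete.cases(X), , drop = FALSE] %*% beta)
  res <- yv - fitted
  structure(list(coef = beta, fitted = fitted, residuals = res,
                 # undefined (NA) for a constant fit, e.g. intercept-only
                 r2 = tryCatch(goodness_of_fit(yv, fitted),
                               error = function(e) NA_real_),
                 sigma2 = sum(res[ok]^2) / sum(ok),
                 df_residual = sum(ok) - ncol(X)),
            class = "static_harmonic_fit")
}

#' Select the temperature lag by goodness of fit
#'
#' Fits one DHR per candidate temperature lag and tabulates the squared
#' correlation between observed and fitted values.  The lag with the
#' highest value wins; exact ties go to the shorter lag.  A fit failure
#' at one lag is recorded in the table, not fatal.
#'
#' @param y area-wide monthly series (numeric or [monthly_series]).
#' @param daily_temp daily temperature data frame (`date`, `temp_c`).
#' @param spec a [dhr_spec] (its `lag` field is overridden per
#'   candidate).
#' @param lags character vector of candidate lags.
#' @param anchor first day of month 1.
#' @param ... passed to [fit_dhr] (e.g. `n_starts`).
#' @return an object of class `lag_selection`: `table` (lag, lag_days,
#'   r2, loglik, converged, error), `best_lag`, and the fit at the best
#'   lag as `best_fit`.
#' @export
select_lag <- function(y, daily_temp, spec = dhr_spec(),
                       lags = c("0d", "7d", "14d", "21d", "1m"),
                       anchor = as.Date("2002-01-01"), ...) {
  yv <- if (inherits(y, "monthly_series")) y$value else as.numeric(y)
  Tn <- length(yv)
  rows <- list()
  fits <- list()
  for (lg in lags) {
    dl <- suppressWarnings(
      lag_temperature(daily_temp, lg, n_months = Tn, anchor = anchor))
    sp <- spec
    sp$lag <- lg
    ft <- tryCatch(fit_dhr(yv, dl, sp, ...), error = function(e) e)
    if (inherits(ft, "error")) {
      rows[[lg]] <- data.frame(lag = lg, lag_days = lag_order_days(lg),
                               r2 = NA_real_, loglik = NA_real_,
                               converged = FALSE,
                               error = conditionMessage(ft))
    } else {
      fits[[lg]] <- ft
      rows[[lg]] <- data.frame(lag = lg, lag_days = lag_order_days(lg),
                               r2 = ft$r2, loglik = ft$loglik,
                               converged = ft$converged, error = "")
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(tab$r2))) stop("all lag fits failed")
  # highest r2; ties broken by shorter lag
  ord <- order(-tab$r2, tab$lag_days, na.last = TRUE)
  best <- tab$lag[ord[1L]]
  structure(list(table = tab, best_lag = best, best_fit = fits[[best]]),
            class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat("Temperature lag selection (squared correlation of fit):\n")
  print.data.frame(x$table[, c("lag", "r2", "loglik", "converged")],
                   row.names = FALSE, digits = 4)
  cat("Best lag:", x$best_lag, "\n")
  invisible(x)
}

#' Seasonal-partition identity of the temperature anomaly
#'
#' Because temperature itself is seasonal, the static model can be
#' written either with the raw temperature series or with a temperature
#' *anomaly* (the residual of temperature regressed on the same
#' harmonic terms).  The two parameterisations partition the seasonal
#' variation differently between the harmonic and temperature terms but
#' span the same column space, so their fitted curves coincide.  This
#' function fits both and reports the maximum absolute difference of
#' the fitted values -- a direct check that stage one adjusts for, rather
#' than explains, the seasonal variation.
#'
#' @inheritParams fit_static_harmonic
#' @return list with `fit_raw`, `fit_anomaly`, the anomaly series
#'   `anomaly`, and `max_abs_diff` of the fitted curves.
#' @export
temperature_anomaly_identity <- function(y, temperature, k = 1L,
                                         trend = FALSE) {
  d <- if (inherits(temperature, "monthly_series"))
    temperature$value else as.numeric(temperature)
  Tn <- length(d)
  t <- seq_len(Tn)
  H <- NULL
  for (p in seq_len(max(1L, k))) {
    H <- cbind(H, cos(p * 2 * pi * t / 12), sin(p * 2 * pi * t / 12))
  }
  ok <- !is.na(d)
  # seasonal component of temperature (no intercept: the anomaly keeps
  # the mean level, which the model intercept absorbs)
  g <- qr.coef(qr(H[ok, , drop = FALSE]), d[ok])
  anomaly <- d - drop(H %*% g)
  # Projection-tolerant fit: aliased columns (e.g. a constant
  # temperature, collinear with the intercept) are dropped by lm but the
  # fitted curve -- the projection onto the column space -- stays defined.
  proj_fit <- function(temp) {
    yv <- if (inherits(y, "monthly_series")) y$value else as.numeric(y)
    X <- cbind(beta = temp, H)
    colnames(X) <- c("beta", paste0(rep(c("A", "B"), k),
                                    rep(seq_len(max(1L, k)), each = 2)))
    if (trend) X <- cbind(X, trend = t)
    fm <- lm(yv ~ X, na.action = stats::na.exclude)
    list(coef = coef(fm), fitted = as.numeric(stats::fitted(fm)),
         r2 = goodness_of_fit(yv, as.numeric(stats::fitted(fm))))
  }
  fit_raw <- proj_fit(d)
  fit_anom <- proj_fit(anomaly)
  diff <- abs(fit_raw$fitted - fit_anom$fitted)
  list(fit_raw = fit_raw, fit_anomaly = fit_anom, anomaly = anomaly,
       max_abs_diff = max(diff, na.rm = TRUE))
}
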