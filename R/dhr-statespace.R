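# Dynamic harmonic regression as a Gaussian state-space model.
#
# Observation:  y_t = Z_t alpha_t + U_t,  U_t ~ N(0, sigma_u^2)
# State:        alpha_t = alpha_{t-1} + eta_t, eta_t ~ N(0, Q) (identity
#               transition: all states are levels)
# State vector: (a, [beta], [trend slope], A_1, B_1, ..., A_k, B_k).
# The intercept a, temperature coefficient beta and optional trend slope
# are constant states (zero innovation variance); each harmonic pair
# (A_p, B_p) shares one random-walk innovation variance.  Initialisation
# is approximately diffuse: a large finite prior variance, with the
# first (state-dimension) innovations excluded from the ML criterion so
# the approximation does not dominate.

#' Specification of a dynamic harmonic regression
#'
#' @param k number of harmonics (1..5; monthly data alias above the
#'   Nyquist frequency for k > 5).  The fundamental frequency is fixed
#'   at `2*pi/12`, one cycle per 12 months.
#' @param include_temperature include the lagged-temperature regressor?
#' @param lag temperature lag choice (see [lag_temperature]); recorded
#'   in the spec and used by [select_lag].
#' @param shared_rw_variance if `TRUE`, one random-walk innovation
#'   variance shared by all harmonics; otherwise one per harmonic
#'   (always shared within each cos/sin pair).
#' @param trend add a constant slope state for a linear time trend?
#'   Off by default: the overall trend is normally left to the
#'   stage-two elapsed-time covariate.
#' @return an object of class `dhr_spec`.
#' @export
dhr_spec <- function(k = 2L, include_temperature = TRUE, lag = "7d",
                     shared_rw_variance = FALSE, trend = FALSE) {
  k <- as.integer(k)
  if (k < 1L || k > 5L)
    stop("invalid argument: `k` must be in 1..5 (Nyquist limit for ",
         "monthly data)")
  lag_days(lag)  # validates
  structure(list(k = k, omega = 2 * pi / 12,
                 include_temperature = isTRUE(include_temperature),
                 lag = lag,
                 shared_rw_variance = isTRUE(shared_rw_variance),
                 trend = isTRUE(trend)),
            class = "dhr_spec")
}

n_hyper <- function(spec) (if (spec$shared_rw_variance) 1L else spec$k) + 1L

#' Build the state-space system for a DHR
#'
#' @param spec a [dhr_spec].
#' @param temperature a [monthly_series] of (lagged) monthly mean
#'   temperatures, or `NULL` when the spec excludes temperature.
#' @param hyper list with `rw_var` (length `k`, or 1 when shared) and
#'   `obs_var`, all nonnegative.
#' @param n_months number of months (defaults to the temperature
#'   series length).
#' @return list with the time-varying observation matrix `Z`
#'   (T x dim), diagonal innovation variances `Qdiag`, `obs_var`,
#'   `state_names` and `dim`.
#' @export
build_state_space <- function(spec, temperature = NULL, hyper,
                              n_months = NULL) {
  stopifnot(inherits(spec, "dhr_spec"))
  rw_var <- as.numeric(hyper$rw_var)
  obs_var <- as.numeric(hyper$obs_var)
  want <- if (spec$shared_rw_variance) 1L else spec$k
  if (length(rw_var) != want)
    stop("hyperparameter vector length mismatch: need ", want,
         " random-walk variance(s) plus the observation variance")
  if (any(rw_var < 0) || obs_var < 0)
    stop("invalid argument: variances must be >= 0")
  rw_var <- rep_len(rw_var, spec$k)
  if (spec$include_temperature) {
    if (is.null(temperature)) stop("temperature series required by spec")
    d <- temperature$value
    if (is.null(n_months)) n_months <- length(d)
    if (length(d) != n_months) stop("temperature length != n_months")
  } else {
    if (is.null(n_months)) stop("`n_months` required without temperature")
    d <- NULL
  }
  t <- seq_len(n_months)
  Z <- matrix(1, n_months, 1L)
  names_ <- "a"
  Qd <- 0
  if (spec$include_temperature) {
    Z <- cbind(Z, d); names_ <- c(names_, "beta"); Qd <- c(Qd, 0)
  }
  if (spec$trend) {
    Z <- cbind(Z, t); names_ <- c(names_, "trend"); Qd <- c(Qd, 0)
  }
  for (p in seq_len(spec$k)) {
    Z <- cbind(Z, cos(p * spec$omega * t), sin(p * spec$omega * t))
    names_ <- c(names_, paste0(c("A", "B"), p))
    Qd <- c(Qd, rw_var[p], rw_var[p])
  }
  colnames(Z) <- names_
  list(Z = Z, Qdiag = Qd, obs_var = obs_var,
       state_names = names_, dim = length(names_), spec = spec)
}

# Rows of Z unusable because a regressor is missing.
obs_missing <- function(ss, y) {
  is.na(y) | apply(ss$Z, 1L, anyNA)
}

#' Kalman filter and prediction-error log-likelihood
#'
#' Runs the Kalman filter for the identity-transition DHR system with an
#' approximately diffuse prior (`1e7` times the sample variance of `y`
#' on each state).  The log-likelihood is the Gaussian prediction-error
#' decomposition with the first `dim` (state-dimension) non-missing
#' innovations excluded, so the finite-prior approximation to the
#' diffuse initial condition does not contaminate the criterion; the
#' all-terms value is also returned.  Missing observations (or missing
#' regressors) skip the measurement update.
#'
#' @param ss a state space from [build_state_space].
#' @param y numeric vector or [monthly_series] of observations.
#' @param diffuse_scale multiple of the sample variance of `y` used as
#'   the prior variance of every state (default `1e7`).  Smaller values
#'   trade diffuseness for numerical headroom, e.g. when comparing
#'   against dense-matrix computations.
#' @return list with `loglik` (burn-in excluded), `loglik_all`,
#'   one-step-ahead innovations `v` and variances `F` (`NA` at missing
#'   months), predicted and filtered state means/covariances, the
#'   burn-in index set, and the prior variance used.
#' @export
kalman_loglik <- function(ss, y, diffuse_scale = 1e7) {
  if (inherits(y, "monthly_series")) y <- y$value
  Tn <- nrow(ss$Z)
  if (length(y) != Tn) stop("series length does not match state space")
  miss <- obs_missing(ss, y)
  if (all(miss)) stop("invalid argument: all observations missing")
  m <- ss$dim
  vy <- var(y, na.rm = TRUE)
  kappa <- diffuse_scale * if (is.finite(vy) && vy > 0) vy else 1
  a <- numeric(m)
  P <- diag(kappa, m)
  Q <- diag(ss$Qdiag, m)
  h <- ss$obs_var
  v <- Fv <- rep(NA_real_, Tn)
  a_pred <- a_filt <- matrix(NA_real_, Tn, m)
  P_pred <- P_filt <- array(NA_real_, c(m, m, Tn))
  ll_terms <- rep(NA_real_, Tn)
  for (t in seq_len(Tn)) {
    # prediction step (identity transition)
    if (t > 1L) P <- P + Q
    a_pred[t, ] <- a
    P_pred[, , t] <- P
    if (!miss[t]) {
      Zt <- ss$Z[t, ]
      PZ <- P %*% Zt
      # the quadratic form is nonnegative in exact arithmetic; clamp
      # roundoff from the large diffuse prior
      Ft <- max(drop(crossprod(Zt, PZ)), 0) + h
      vt <- y[t] - drop(Zt %*% a)
      if (Ft <= 0) stop("non-positive innovation variance; degenerate model")
      K <- drop(PZ / Ft)
      a <- a + K * vt
      # Joseph-form update: numerically stable (keeps P PSD even with a
      # near-zero observation variance)
      ImKZ <- diag(m) - tcrossprod(K, Zt)
      P <- ImKZ %*% P %*% t(ImKZ) + tcrossprod(K) * h
      P <- (P + t(P)) / 2
      v[t] <- vt
      Fv[t] <- Ft
      ll_terms[t] <- -0.5 * (log(2 * pi) + log(Ft) + vt^2 / Ft)
    }
    a_filt[t, ] <- a
    P_filt[, , t] <- P
  }
  obs_idx <- which(!miss)
  burn <- obs_idx[seq_len(min(m, length(obs_idx)))]
  keep <- setdiff(obs_idx, burn)
  list(loglik = sum(ll_terms[keep]),
       loglik_all = sum(ll_terms[obs_idx]),
       v = v, F = Fv,
       a_pred = a_pred, P_pred = P_pred,
       a_filt = a_filt, P_filt = P_filt,
       burn_in = burn, missing = miss, kappa = kappa)
}

#' Fixed-interval Kalman smoother
#'
#' Backward recursion giving the smoothed state means and variances and
#' the smoothed fitted values (observation vector dotted with the
#' smoothed state).  Smoothed variances never exceed the filtered ones
#' on the diagonal; months with missing observations still receive
#' fitted values.
#'
#' @inheritParams kalman_loglik
#' @param kf optional precomputed [kalman_loglik] output.
#' @return list with `states` (T x dim smoothed means), `state_var`
#'   (T x dim smoothed variance diagonals), `fitted` (smoothed signal
#'   `Z_t alpha_t`), `fitted_var`, plus the filter output as `filter`.
#' @export
kalman_smooth <- function(ss, y, kf = NULL, diffuse_scale = 1e7) {
  if (inherits(y, "monthly_series")) y <- y$value
  if (is.null(kf)) kf <- kalman_loglik(ss, y, diffuse_scale = diffuse_scale)
  Tn <- nrow(ss$Z)
  m <- ss$dim
  r <- numeric(m)
  N <- matrix(0, m, m)
  alphahat <- matrix(NA_real_, Tn, m, dimnames = list(NULL, ss$state_names))
  Vdiag <- matrix(NA_real_, Tn, m)
  fitted <- fitted_var <- rep(NA_real_, Tn)
  for (t in rev(seq_len(Tn))) {
    P <- kf$P_pred[, , t]
    if (!kf$missing[t]) {
      Zt <- ss$Z[t, ]
      Ft <- kf$F[t]
      K <- drop(P %*% Zt) / Ft
      L <- diag(m) - tcrossprod(K, Zt)
      r <- Zt * (kf$v[t] / Ft) + drop(crossprod(L, r))
      N <- tcrossprod(Zt) / Ft + crossprod(L, N %*% L)
    }
    ah <- kf$a_pred[t, ] + drop(P %*% r)
    V <- P - P %*% N %*% P
    alphahat[t, ] <- ah
    Vdiag[t, ] <- pmax(diag(V), 0)
    Zt <- ss$Z[t, ]
    if (!anyNA(Zt)) {
      fitted[t] <- drop(Zt %*% ah)
      fitted_var[t] <- drop(crossprod(Zt, V %*% Zt))
    }
    # shift r, N from r_{t-1} at the observation time to the prediction
    # time of t-1: identity transition makes this a no-op.
  }
  list(states = alphahat, state_var = Vdiag,
       fitted = fitted, fitted_var = pmax(fitted_var, 0), filter = kf)
}
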