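# Independent brute-force oracles used to check the fast implementations.
# These deliberately avoid the package's Kalman/profiling code paths:
# everything is dense joint-Gaussian algebra or naive enumeration.

# Log-density of y under N(mu, S) via Cholesky.
dense_mvn_logpdf <- function(y, mu, S) {
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Joint covariance of the observations implied by the DHR state-space
# model: identity transition, diagonal innovation covariance Qdiag,
# initial state N(0, kappa I).  Cov(y_t, y_u) =
#   Z_t (kappa I + min(t,u-1) Q) Z_u' + sigma_u^2 1{t=u}.
dhr_joint_cov <- function(Z, Qdiag, obs_var, kappa) {
  Tn <- nrow(Z)
  S <- matrix(0, Tn, Tn)
  for (t in seq_len(Tn)) for (u in seq_len(Tn)) {
    cum <- kappa + (min(t, u) - 1) * Qdiag
    S[t, u] <- sum(Z[t, ] * cum * Z[u, ])
  }
  S + diag(obs_var, Tn)
}

# Burn-in-excluded prediction-error log-likelihood by dense algebra:
# log p(y_{(d+1)..T} | y_{1..d}) = log p(y) - log p(y_{1..d}).
oracle_dhr_loglik <- function(Z, Qdiag, obs_var, kappa, y) {
  S <- dhr_joint_cov(Z, Qdiag, obs_var, kappa)
  d <- ncol(Z)
  head_idx <- seq_len(d)
  dense_mvn_logpdf(y, rep(0, length(y)), S) -
    dense_mvn_logpdf(y[head_idx], rep(0, d), S[head_idx, head_idx])
}

# Smoothed signal means E[Z_t alpha_t | y] by dense conditioning:
# the signal s = Z alpha has Cov(s, y) = Cov(s, s), y = s + noise.
oracle_dhr_smoothed_signal <- function(Z, Qdiag, obs_var, kappa, y) {
  S <- dhr_joint_cov(Z, Qdiag, obs_var, kappa)
  Css <- S - diag(obs_var, nrow(Z))
  as.numeric(Css %*% solve(S, y))
}

# Dense ML log-likelihood of the random-intercept model at given
# parameters: V = sigma_e2 * (I + lambda Z Z') with Z the group
# indicator matrix.
oracle_mixed_loglik <- function(y, X, beta, group, sigma_e2, lambda) {
  Zg <- outer(group, sort(unique(group)), "==") * 1
  V <- sigma_e2 * (diag(length(y)) + lambda * tcrossprod(Zg))
  dense_mvn_logpdf(y, as.numeric(X %*% beta), V)
}

# Naive normal-equations least squares.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Naive binned variogram: double loop over all pairs.
oracle_binned_variogram <- function(values, east, north, breaks) {
  n <- length(values)
  nb <- length(breaks) - 1L
  sums <- cnt <- rep(0, nb)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((east[i] - east[j])^2 + (north[i] - north[j])^2)
    b <- findInterval(d, breaks)
    if (b >= 1 && b <= nb && d < breaks[nb + 1L]) {
      sums[b] <- sums[b] + 0.5 * (values[i] - values[j])^2
      cnt[b] <- cnt[b] + 1
    }
  }
  ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
}

# One-way balanced ANOVA estimators of the variance components
# (method of moments; equals REML for a balanced intercept-only design
# when the between-group estimate is interior).
oracle_anova_varcomp <- function(y, group) {
  J <- length(unique(group))
  Tn <- length(y) / J
  gm <- tapply(y, group, mean)
  msw <- sum((y - gm[as.character(group)])^2) / (J * (Tn - 1))
  msb <- Tn * sum((gm - mean(y))^2) / (J - 1)
  c(sigma_e2 = msw, sigma_b2 = (msb - msw) / Tn)
}

# Small default panel used by several tests.
small_sim <- function(seed = 11, n = 8L, Tm = 24L, ...) {
  gen_panel(panel_gen_config(n_practices = n, n_months = Tm,
                             seed = seed, ...))
}
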