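# Stage two: random-intercept linear mixed model with the stage-one
# fitted curve as an offset.
#
# Model:  y_jt = offset_t + x_jt' a + b_j + eps_jt,
#         b_j ~ N(0, sigma_b^2),  eps_jt ~ N(0, sigma_e^2) independent.
#
# Estimation profiles the (RE)ML criterion down to the single ratio
# lambda = sigma_b^2 / sigma_e^2: given lambda the fixed effects are
# closed-form GLS and sigma_e^2 is closed form, so the fit is a
# one-dimensional optimisation on log(lambda).  The marginal covariance
# is block compound-symmetric, V_j = sigma_e^2 (I + lambda J), and all
# cross-products use the Woodbury form
# V0_j^{-1} = I - w_j J, w_j = lambda / (1 + lambda n_j).

#' Specification of the stage-two mixed model
#'
#' @param covariates character vector of covariate columns to include
#'   as fixed effects (an intercept is always added).
#' @param offset the stage-one fitted area-wide curve: a
#'   [monthly_series], a `dhr_fit`, or a numeric vector indexed by
#'   month.  Its coefficient is fixed at 1, never estimated.
#' @param criterion `"REML"` (default; unbiased variance components) or
#'   `"ML"` (for likelihood comparisons).
#' @param level central interval level for BLUP prediction intervals.
#' @return an object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(covariates = character(), offset,
                             criterion = c("REML", "ML"), level = 0.95) {
  criterion <- match.arg(criterion)
  if (!(level > 0 && level < 1))
    stop("invalid argument: `level` must be in (0, 1)")
  if (inherits(offset, "dhr_fit")) offset <- offset$fitted
  if (inherits(offset, "monthly_series")) offset <- offset$value
  structure(list(covariates = covariates, offset = as.numeric(offset),
                 criterion = criterion, level = level),
            class = "mixed_model_spec")
}

#' Fit the random-intercept mixed model with offset
#'
#' Subtracts the offset from the outcome, then maximises the profiled
#' REML or ML criterion over the variance ratio
#' \eqn{\lambda = \sigma_b^2/\sigma_\varepsilon^2} by one-dimensional
#' optimisation on \eqn{\log\lambda}, with closed-form GLS fixed
#' effects and residual variance given \eqn{\lambda}.  Standard errors
#' are Wald (GLS covariance); t and two-sided p values use residual
#' degrees of freedom N - p.
#'
#' @param panel a `practice_panel`.
#' @param spec a [mixed_model_spec]; its offset must cover every month
#'   present in the panel.
#' @return an object of class `mixed_model_fit` with components
#'   `coefficients` (data frame: estimate, se, t, p), `sigma_b2`,
#'   `sigma_e2`, `lambda`, `criterion`, `logLik` (the maximised
#'   criterion), `blups` (practice, blup, cond_var, n_obs), `residuals`
#'   (practice, month, easting, northing, residual), `boundary` (TRUE
#'   when the variance ratio was estimated at the lower boundary), and
#'   bookkeeping needed by the diagnostics.
#' @examples
#' sim <- gen_panel(panel_gen_config(n_practices = 8, n_months = 24,
#'                                   seed = 5))
#' sp <- mixed_model_spec(c("income", "age"), offset = sim$truth$mu_t)
#' fit <- fit_random_intercept(sim$panel, sp)
#' fit$coefficients
#' @export
fit_random_intercept <- function(panel, spec) {
  stopifnot(inherits(panel, "practice_panel"),
            inherits(spec, "mixed_model_spec"))
  rec <- panel$records[!is.na(panel$records$log_rate), , drop = FALSE]
  if (length(unique(rec$practice_id)) < 2L)
    stop("need at least 2 practices")
  if (max(rec$month) > length(spec$offset) || anyNA(spec$offset[rec$month]))
    stop("offset not defined for every month present in the panel")
  miss <- setdiff(spec$covariates, names(rec))
  if (length(miss))
    stop("covariate(s) not in panel: ", paste(miss, collapse = ", "))

  y <- rec$log_rate - spec$offset[rec$month]
  X <- cbind("(Intercept)" = 1,
             as.matrix(rec[, spec$covariates, drop = FALSE]))
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("rank-deficient fixed-effects design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):p]], collapse = ", "))
  g <- factor(rec$practice_id)
  n_j <- as.integer(table(g))
  groups <- levels(g)
  N <- length(y)

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  Sx <- rowsum(X, g)                 # group sums of columns, J x p
  Sy <- as.numeric(rowsum(y, g))     # group sums of y

  profile <- function(lambda) {
    w <- lambda / (1 + lambda * n_j)
    A <- XtX - crossprod(Sx, Sx * w)
    b <- Xty - crossprod(Sx, Sy * w)
    beta <- solve(A, b)
    rss <- yty - sum(w * Sy^2) - sum(beta * b)
    logdetV0 <- sum(log1p(lambda * n_j))
    list(beta = beta, rss = max(rss, 1e-300), A = A, logdetV0 = logdetV0)
  }
  # Harville's REML form carries a +log|X'X| constant, which makes the
  # criterion value invariant to full-rank reparameterisation of X.
  logdetXtX <- as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
  crit <- function(loglambda) {
    pr <- profile(exp(loglambda))
    if (spec$criterion == "ML") {
      s2 <- pr$rss / N
      0.5 * (N * log(2 * pi * s2) + pr$logdetV0 + N)
    } else {
      s2 <- pr$rss / (N - p)
      0.5 * ((N - p) * log(2 * pi * s2) + pr$logdetV0 +
             as.numeric(determinant(pr$A, logarithm = TRUE)$modulus) -
             logdetXtX + (N - p))
    }
  }
  opt <- optimize(crit, interval = c(-30, 15), tol = 1e-10)
  # the log-scale search cannot reach lambda = 0 exactly; compare with
  # the boundary explicitly
  c0 <- crit(-Inf)
  boundary <- c0 <= opt$objective || opt$minimum <= -30 + 1e-6
  lambda <- if (c0 <= opt$objective) 0 else exp(opt$minimum)
  critval <- min(c0, opt$objective)

  pr <- profile(lambda)
  df <- N - p
  sigma_e2 <- pr$rss / (if (spec$criterion == "ML") N else df)
  sigma_b2 <- lambda * sigma_e2
  covb <- sigma_e2 * solve(pr$A)
  est <- as.numeric(pr$beta)
  se <- sqrt(diag(covb))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      t_value = tval, p_value = pval)

  # BLUPs: shrinkage of the group mean marginal residual
  rfix <- y - drop(X %*% pr$beta)
  rbar <- as.numeric(rowsum(rfix, g)) / n_j
  shrink <- lambda * n_j / (1 + lambda * n_j)
  blup <- shrink * rbar
  cond_var <- sigma_b2 / (1 + lambda * n_j)   # = sb2*se2/(se2 + n sb2)
  blups <- data.frame(practice_id = groups, blup = blup,
                      cond_var = cond_var, n_obs = n_j)

  resids <- rfix - blup[as.integer(g)]
  loc <- panel$locations[match(rec$practice_id,
                               panel$locations$practice_id), ]
  residuals <- data.frame(practice_id = rec$practice_id,
                          month = rec$month,
                          easting = loc$easting, northing = loc$northing,
                          fitted = rec$log_rate - resids,
                          residual = resids)

  structure(list(coefficients = coefs, sigma_b2 = sigma_b2,
                 sigma_e2 = sigma_e2, lambda = lambda,
                 criterion = spec$criterion, logLik = -critval,
                 blups = blups, residuals = residuals,
                 boundary = boundary, level = spec$level,
                 n = N, p = p, df_residual = df,
                 locations = panel$locations, spec = spec),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept mixed model (%s), %d records, %d practices\n",
    x$criterion, x$n, nrow(x$blups)))
  printdf <- x$coefficients
  printdf$p_value <- format.pval(printdf$p_value, digits = 3)
  print.data.frame(printdf, row.names = FALSE, digits = 4)
  cat(sprintf("  sigma_b^2 = %.5g, sigma_eps^2 = %.5g%s\n",
              x$sigma_b2, x$sigma_e2,
              if (x$boundary) "  [variance ratio at boundary]" else ""))
  invisible(x)
}

#' BLUPs with prediction intervals, ordered by conditional mean
#'
#' Returns the practice-level random-effect predictions (conditional
#' means) with central prediction intervals from the conditional
#' variance, sorted ascending by the conditional mean -- the layout of
#' the caterpillar plot used to inspect practice effects.
#'
#' @param fit a `mixed_model_fit`.
#' @param level interval level (defaults to the level in the fit spec).
#' @return data frame: `practice_id`, `blup`, `cond_sd`, `lower`,
#'   `upper`, sorted ascending by `blup`.
#' @export
blup_intervals <- function(fit, level = NULL) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (is.null(level)) level <- fit$level
  z <- qnorm((1 + level) / 2)
  b <- fit$blups
  out <- data.frame(practice_id = b$practice_id, blup = b$blup,
                    cond_sd = sqrt(b$cond_var),
                    lower = b$blup - z * sqrt(b$cond_var),
                    upper = b$blup + z * sqrt(b$cond_var))
  out <- out[order(out$blup), ]
  rownames(out) <- NULL
  out
}

#' Descriptive residual diagnostics for the mixed model
#'
#' Emits the raw material for the standard linear-model checks --
#' linearity, homoscedasticity, approximate normality, and absence of
#' residual autocorrelation -- with no pass/fail verdict attached:
#' binned residual means and SDs against fitted values, normal-quantile
#' pairs, and the per-practice residual autocorrelation function.
#'
#' @param fit a `mixed_model_fit`.
#' @param n_bins number of fitted-value bins.
#' @param max_lag maximum ACF lag (capped at the series length minus 1).
#' @return list with `binned` (bin centre, mean, sd, se, n), `qq`
#'   (theoretical and sample quantiles), and `acf_by_practice` (matrix,
#'   lag 0..max_lag by practice).
#' @export
residual_checks <- function(fit, n_bins = 10L, max_lag = 12L) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  r <- fit$residuals$residual
  f <- fit$residuals$fitted
  bins <- cut(f, breaks = quantile(f, probs = seq(0, 1, length.out =
                                                    n_bins + 1L)),
              include.lowest = TRUE)
  binned <- data.frame(
    centre = tapply(f, bins, mean),
    mean = tapply(r, bins, mean),
    sd = tapply(r, bins, sd),
    n = as.integer(table(bins)))
  binned$se <- binned$sd / sqrt(binned$n)
  qq <- data.frame(theoretical = qnorm(ppoints(length(r))),
                   sample = sort(r) / sd(r))
  by_p <- split(fit$residuals[order(fit$residuals$month), ],
                fit$residuals$practice_id)
  acfs <- vapply(by_p, function(d) {
    ml <- min(max_lag, nrow(d) - 1L)
    a <- rep(NA_real_, max_lag + 1L)
    a[seq_len(ml + 1L)] <- residual_acf(d$residual[order(d$month)], ml)
    a
  }, numeric(max_lag + 1L))
  rownames(acfs) <- paste0("lag", 0:max_lag)
  list(binned = binned, qq = qq, acf_by_practice = acfs)
}
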