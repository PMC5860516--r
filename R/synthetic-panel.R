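# Synthetic practice-month panels with known ground truth.
#
# The generator mirrors the generative structure the two-stage model
# assumes: an area-wide seasonal path with drifting harmonic coefficients
# and a shared (lagged) temperature driver, practice-level covariate
# effects, normal practice random intercepts, and residuals that are iid,
# spatially correlated, or separably spatiotemporally correlated.

#' Configuration for the synthetic panel generator
#'
#' Defaults reproduce the shape of the motivating study: 63 practices
#' observed over 55 months (3,465 records) in a 20 km square window,
#' monthly log prescribing rates with winter/spring peaks whose amplitude
#' and phase drift between years, a 7-day-lagged temperature driver, an
#' overall downward time trend carried by the elapsed-time covariate,
#' and practice random intercepts.
#'
#' @param n_practices number of practices (>= 2).
#' @param n_months number of months (>= 13: at least one full annual
#'   cycle plus one month).
#' @param extent_m side length of the square study window, metres.
#' @param k number of harmonics in the seasonal path (1..5).
#' @param intercept area-wide intercept `a` on the log-rate scale.
#' @param beta_temp temperature coefficient (per degree C); negative
#'   values give higher rates in colder months.
#' @param temp_lag lag applied to the daily temperature before monthly
#'   averaging when building the true path (`"0d"`, `"7d"`, `"14d"`,
#'   `"21d"`, `"1m"`, or a day count).
#' @param rw_sd random-walk innovation SD for the harmonic coefficients,
#'   one value per harmonic (shared within each cos/sin pair); recycled
#'   to length `k`.
#' @param init_coef means of the initial harmonic coefficients
#'   (A1, B1, A2, B2, ...), length `2k`; defaults put the main peak in
#'   winter with a secondary spring feature.
#' @param init_sd SD of the normal draw for the initial coefficients,
#'   per harmonic (recycled to length `k`); defaults to half of each
#'   harmonic's mean amplitude, so cycles start at realistic size.
#' @param obs_sd SD of the area-level observation noise `U_t` used for
#'   the emitted area-wide series.
#' @param covariate_effects named numeric vector of fixed effects for
#'   the practice-level covariates; names must be a subset of
#'   `air_pollution, traffic, income, employment, education, age,
#'   sex_ratio, time_elapsed`.
#' @param sigma_b SD of the practice random intercepts.
#' @param sigma_eps SD of the practice-month residuals.
#' @param resid_type residual correlation switch: `"iid"`, `"spatial"`
#'   (exponential in distance), or `"spatiotemporal"` (separable
#'   exponential-in-space times AR(1)-in-time).
#' @param spatial_range_m range parameter of the exponential spatial
#'   correlation, metres.
#' @param ar_coef temporal AR(1) coefficient, in (-1, 1).
#' @param anchor first day of study month 1.
#' @param temp_noise_sd daily temperature noise SD passed to
#'   [gen_temperature].
#' @param seed integer RNG seed for the whole generator.
#' @return a list of class `panel_gen_config`.
#' @export
panel_gen_config <- function(n_practices = 63L, n_months = 55L,
                             extent_m = 20000, k = 2L,
                             intercept = 3.0, beta_temp = -0.02,
                             temp_lag = "7d",
                             rw_sd = c(0.02, 0.01),
                             init_coef = c(0.12, 0.05, -0.04, 0.03),
                             init_sd = NULL,
                             obs_sd = 0.02,
                             covariate_effects = c(
                               air_pollution = 0.001, traffic = 0,
                               income = 1.8, employment = 2.3,
                               education = 0, age = 0.03,
                               sex_ratio = 0, time_elapsed = -4e-4),
                             sigma_b = 0.15, sigma_eps = 0.10,
                             resid_type = c("iid", "spatial",
                                            "spatiotemporal"),
                             spatial_range_m = 5000, ar_coef = 0.6,
                             anchor = as.Date("2002-01-01"),
                             temp_noise_sd = 2,
                             seed = 1L) {
  resid_type <- match.arg(resid_type)
  k <- as.integer(k)
  if (n_practices < 2) stop("invalid argument: `n_practices` must be >= 2")
  if (n_months < 13)
    stop("invalid argument: `n_months` must be >= 13 (one cycle plus one)")
  if (extent_m <= 0) stop("invalid argument: `extent_m` must be positive")
  if (k < 1 || k > 5) stop("invalid argument: `k` must be in 1..5")
  rw_sd <- rep_len(rw_sd, k)
  if (length(init_coef) != 2L * k) {
    init_coef <- rep_len(init_coef, 2L * k)
  }
  if (is.null(init_sd)) {
    amp <- sqrt(init_coef[2 * seq_len(k) - 1]^2 + init_coef[2 * seq_len(k)]^2)
    init_sd <- pmax(amp / 2, 1e-3)
  }
  init_sd <- rep_len(init_sd, k)
  sds <- c(rw_sd, init_sd, obs_sd, sigma_b, sigma_eps, temp_noise_sd)
  if (any(sds < 0)) stop("invalid argument: all SDs must be >= 0")
  if (abs(ar_coef) >= 1)
    stop("invalid argument: `ar_coef` must be in (-1, 1)")
  known <- c("air_pollution", "traffic", "income", "employment",
             "education", "age", "sex_ratio", "time_elapsed")
  if (is.null(names(covariate_effects)) ||
      !all(names(covariate_effects) %in% known))
    stop("invalid argument: `covariate_effects` names must be a subset of ",
         paste(known, collapse = ", "))
  cfg <- list(n_practices = as.integer(n_practices),
              n_months = as.integer(n_months), extent_m = extent_m,
              k = k, intercept = intercept, beta_temp = beta_temp,
              temp_lag = temp_lag, rw_sd = rw_sd, init_coef = init_coef,
              init_sd = init_sd, obs_sd = obs_sd,
              covariate_effects = covariate_effects,
              sigma_b = sigma_b, sigma_eps = sigma_eps,
              resid_type = resid_type, spatial_range_m = spatial_range_m,
              ar_coef = ar_coef, anchor = as.Date(anchor),
              temp_noise_sd = temp_noise_sd, seed = as.integer(seed))
  class(cfg) <- "panel_gen_config"
  cfg
}

#' Generate uniform practice locations
#'
#' `n` distinct points drawn uniformly over the square `[0, extent_m]^2`.
#'
#' @param n number of practices (>= 2).
#' @param extent_m side length of the square window, metres.
#' @param seed integer RNG seed.
#' @return data frame with columns `practice_id`, `easting`, `northing`.
#' @export
gen_locations <- function(n, extent_m = 20000, seed = NULL) {
  if (!is.numeric(n) || n < 2) stop("invalid argument: `n` must be >= 2")
  n <- as.integer(n)
  xy <- with_seed(seed, {
    repeat {
      m <- cbind(runif(n, 0, extent_m), runif(n, 0, extent_m))
      if (!anyDuplicated(m)) break    # continuous draw; duplicates measure 0
    }
    m
  })
  data.frame(practice_id = sprintf("P%02d", seq_len(n)),
             easting = xy[, 1L], northing = xy[, 2L])
}

# Practice-level covariates: deprivation measures as smooth spatial
# fields (logistic transforms of low-order polynomials in the scaled
# coordinates) plus noise, demographic covariates as noisy constants.
gen_covariates <- function(loc, extent_m, n_months) {
  n <- nrow(loc)
  u <- loc$easting / extent_m
  v <- loc$northing / extent_m
  logistic <- function(x) 1 / (1 + exp(-x))
  income     <- 0.05 + 0.4 * logistic(2.5 * (u - 0.5) + 1.5 * v - 1 +
                                      rnorm(n, sd = 0.4))
  employment <- 0.05 + 0.35 * logistic(2.0 * (u - 0.4) + 2.0 * (v - 0.6) +
                                       rnorm(n, sd = 0.4))
  education  <- 0.05 + 0.4 * logistic(-2.0 * (u - 0.5) + 1.0 * (v - 0.3) +
                                      rnorm(n, sd = 0.4))
  age       <- 38 + 4 * (v - 0.5) + rnorm(n, sd = 1.5)
  sex_ratio <- 1 + rnorm(n, sd = 0.04)
  traffic   <- exp(rnorm(n, mean = log(500), sd = 0.5)) * (0.5 + u)
  # Area-wide monthly air pollution (PM10): mild winter peak plus noise.
  t <- seq_len(n_months)
  pm10 <- 18 + 4 * cos(2 * pi * t / 12) + rnorm(n_months, sd = 2)
  list(static = data.frame(practice_id = loc$practice_id,
                           income = income, employment = employment,
                           education = education, age = age,
                           sex_ratio = sex_ratio, traffic = traffic),
       air_pollution = pm10)
}

#' Generate a synthetic practice-month panel with ground truth
#'
#' Builds the area-wide seasonal path
#' \deqn{a + \beta d(t) + \sum_{p=1}^{k} \{A_{p,t}\cos(p\omega t) +
#'       B_{p,t}\sin(p\omega t)\}, \quad \omega = 2\pi/12,}
#' with the harmonic coefficients following independent random walks and
#' \eqn{d(t)} the lagged monthly mean temperature, then sets each
#' practice's log rate to the area path plus covariate effects, a normal
#' practice random intercept, and a residual that is iid, spatially
#' correlated (exponential in distance), or separably spatiotemporal
#' (exponential in space, AR(1) in time).  The true states and
#' parameters are always returned alongside the panel so that recovery
#' tests never have to re-derive truth from the data.
#'
#' @param cfg a [panel_gen_config].
#' @return a list of class `panel_sim` with elements
#'   \describe{
#'     \item{panel}{a `practice_panel` (see [as_practice_panel]).}
#'     \item{area_series}{[monthly_series] of the area path plus
#'       observation noise `U_t` (for stage-one fitting in isolation).}
#'     \item{daily_temp}{the daily temperature series.}
#'     \item{truth}{list of true states and parameters: `mu_t` (area
#'       path), `A`, `B` (T x k coefficient paths), `d_lagged`, `b`
#'       (random intercepts), `eps` (practice x month residual matrix),
#'       and the configuration.}
#'   }
#' @examples
#' sim <- gen_panel(panel_gen_config(n_practices = 5, n_months = 24,
#'                                   seed = 7))
#' nrow(sim$panel$records)
#' @export
gen_panel <- function(cfg = panel_gen_config()) {
  stopifnot(inherits(cfg, "panel_gen_config"))
  n <- cfg$n_practices
  Tm <- cfg$n_months
  k <- cfg$k
  omega <- 2 * pi / 12

  daily <- gen_temperature(Tm, seed = substream_seed(cfg$seed, "temperature"),
                           anchor = cfg$anchor,
                           noise_sd = cfg$temp_noise_sd)
  dlag <- suppressWarnings(
    lag_temperature(daily, cfg$temp_lag, n_months = Tm, anchor = cfg$anchor))
  loc <- gen_locations(n, cfg$extent_m,
                       seed = substream_seed(cfg$seed, "locations"))

  out <- with_seed(substream_seed(cfg$seed, "generator"), {
    A <- B <- matrix(0, Tm, k)
    for (p in seq_len(k)) {
      A[1, p] <- rnorm(1, cfg$init_coef[2 * p - 1], cfg$init_sd[p])
      B[1, p] <- rnorm(1, cfg$init_coef[2 * p],     cfg$init_sd[p])
      if (Tm > 1) {
        A[, p] <- A[1, p] + c(0, cumsum(rnorm(Tm - 1, sd = cfg$rw_sd[p])))
        B[, p] <- B[1, p] + c(0, cumsum(rnorm(Tm - 1, sd = cfg$rw_sd[p])))
      }
    }
    t <- seq_len(Tm)
    seas <- rowSums(vapply(seq_len(k), function(p)
      A[, p] * cos(p * omega * t) + B[, p] * sin(p * omega * t),
      numeric(Tm)))
    mu_t <- cfg$intercept + cfg$beta_temp * dlag$value + seas
    area <- mu_t + rnorm(Tm, sd = cfg$obs_sd)

    covs <- gen_covariates(loc, cfg$extent_m, Tm)
    b <- rnorm(n, sd = cfg$sigma_b)

    eps <- switch(cfg$resid_type,
      iid = matrix(rnorm(n * Tm, sd = cfg$sigma_eps), n, Tm),
      spatial = {
        D <- as.matrix(dist(loc[, c("easting", "northing")]))
        L <- chol(exp(-D / cfg$spatial_range_m) + diag(1e-10, n))
        cfg$sigma_eps * crossprod(L, matrix(rnorm(n * Tm), n, Tm))
      },
      spatiotemporal = {
        D <- as.matrix(dist(loc[, c("easting", "northing")]))
        L <- chol(exp(-D / cfg$spatial_range_m) + diag(1e-10, n))
        phi <- cfg$ar_coef
        E <- matrix(0, n, Tm)
        E[, 1] <- crossprod(L, rnorm(n))
        for (tt in 2:Tm)
          E[, tt] <- phi * E[, tt - 1] +
            sqrt(1 - phi^2) * crossprod(L, rnorm(n))
        cfg$sigma_eps * E
      })

    list(A = A, B = B, mu_t = mu_t, area = area, covs = covs,
         b = b, eps = eps)
  })

  # Long-format records with the full covariate set; effects not named
  # in cfg$covariate_effects contribute zero but the covariates are
  # still emitted (analysts choose the subset at fit time).
  eff <- setNames(rep(0, 8), c("air_pollution", "traffic", "income",
                               "employment", "education", "age",
                               "sex_ratio", "time_elapsed"))
  eff[names(cfg$covariate_effects)] <- cfg$covariate_effects
  st <- out$covs$static
  rec <- expand.grid(practice = seq_len(n), month = seq_len(Tm))
  records <- data.frame(
    practice_id = st$practice_id[rec$practice],
    month = rec$month,
    air_pollution = out$covs$air_pollution[rec$month],
    traffic = st$traffic[rec$practice],
    income = st$income[rec$practice],
    employment = st$employment[rec$practice],
    education = st$education[rec$practice],
    age = st$age[rec$practice],
    sex_ratio = st$sex_ratio[rec$practice],
    time_elapsed = rec$month)
  xb <- as.matrix(records[, names(eff)]) %*% eff
  records$log_rate <- out$mu_t[rec$month] + as.numeric(xb) +
    out$b[rec$practice] + out$eps[cbind(rec$practice, rec$month)]
  records <- records[order(records$practice_id, records$month),
                     c("practice_id", "month", "log_rate", names(eff))]
  rownames(records) <- NULL

  panel <- as_practice_panel(records, loc, anchor = cfg$anchor)
  structure(list(
    panel = panel,
    area_series = monthly_series(seq_len(Tm), out$area, anchor = cfg$anchor),
    daily_temp = daily,
    truth = list(cfg = cfg, mu_t = out$mu_t, A = out$A, B = out$B,
                 d_lagged = dlag$value, b = setNames(out$b, st$practice_id),
                 eps = out$eps, effects = eff)),
    class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cfg <- x$truth$cfg
  cat(sprintf(
    "Synthetic panel: %d practices x %d months = %d records (%s residuals)\n",
    cfg$n_practices, cfg$n_months, nrow(x$panel$records), cfg$resid_type))
  invisible(x)
}
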