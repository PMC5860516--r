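# Stage two: profiled (RE)ML random-intercept model with offset.

panel_from_matrix <- function(Y, loc, offset = NULL, covars = NULL) {
  # Y: practices x months outcome matrix
  n <- nrow(Y); Tm <- ncol(Y)
  rec <- expand.grid(practice = seq_len(n), month = seq_len(Tm))
  records <- data.frame(practice_id = loc$practice_id[rec$practice],
                        month = rec$month,
                        log_rate = Y[cbind(rec$practice, rec$month)])
  if (!is.null(covars)) records <- cbind(records, covars[rec$practice, ,
                                                         drop = FALSE])
  records <- records[order(records$practice_id, records$month), ]
  as_practice_panel(records, loc)
}

test_that("ML criterion equals the dense block compound-symmetry
           log-density on a 5 x 12 panel", {
  set.seed(21)
  n <- 5L; Tm <- 12L
  loc <- gen_locations(n, seed = 1)
  x1 <- rnorm(n)
  Y <- outer(0.5 * x1 + rnorm(n, sd = 0.3), rep(1, Tm)) +
    matrix(rnorm(n * Tm, sd = 0.2), n, Tm)
  covars <- data.frame(x1 = x1)
  panel <- panel_from_matrix(Y, loc, covars = covars)
  off <- rep(0, Tm)
  fit <- fit_random_intercept(panel,
                              mixed_model_spec("x1", offset = off,
                                               criterion = "ML"))
  rec <- panel$records
  X <- cbind(1, rec$x1)
  oracle <- oracle_mixed_loglik(rec$log_rate, X,
                                fit$coefficients$estimate,
                                rec$practice_id,
                                fit$sigma_e2, fit$lambda)
  expect_equal(fit$logLik, oracle, tolerance = 1e-6)
})

test_that("REML variance components equal the closed-form balanced
           ANOVA estimators when interior", {
  set.seed(22)
  n <- 12L; Tm <- 20L
  loc <- gen_locations(n, seed = 2)
  b <- rnorm(n, sd = 0.4)
  Y <- outer(b, rep(1, Tm)) + matrix(rnorm(n * Tm, sd = 0.25), n, Tm)
  panel <- panel_from_matrix(Y, loc)
  fit <- fit_random_intercept(
    panel, mixed_model_spec(character(), offset = rep(0, Tm)))
  vc <- oracle_anova_varcomp(panel$records$log_rate,
                             panel$records$practice_id)
  expect_gt(vc["sigma_b2"], 0)  # interior case
  expect_equal(fit$sigma_e2, as.numeric(vc["sigma_e2"]), tolerance = 1e-6)
  expect_equal(fit$sigma_b2, as.numeric(vc["sigma_b2"]), tolerance = 1e-6)
})

test_that("estimates, SEs and variance components agree with lme4", {
  skip_if_not_installed("lme4")
  sim <- small_sim(seed = 23, n = 15L, Tm = 30L)
  sp <- mixed_model_spec(c("income", "age", "time_elapsed"),
                         offset = sim$truth$mu_t)
  fit <- fit_random_intercept(sim$panel, sp)
  rec <- sim$panel$records
  rec$yadj <- rec$log_rate - sim$truth$mu_t[rec$month]
  lf <- lme4::lmer(yadj ~ income + age + time_elapsed +
                     (1 | practice_id), data = rec, REML = TRUE)
  expect_equal(fit$coefficients$estimate,
               as.numeric(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$coefficients$se,
               as.numeric(coef(summary(lf))[, "Std. Error"]),
               tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma_b2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-4)
  # BLUPs against lme4's conditional means
  re <- lme4::ranef(lf)$practice_id
  expect_equal(fit$blups$blup[match(rownames(re),
                                    fit$blups$practice_id)],
               re[, 1], tolerance = 1e-4)
})

test_that("data generated without practice effects drive the variance
           ratio to the boundary and GLS to OLS", {
  set.seed(24)
  n <- 10L; Tm <- 30L
  loc <- gen_locations(n, seed = 3)
  x1 <- rnorm(n)
  E <- matrix(rnorm(n * Tm, sd = 0.3), n, Tm)
  E <- E - rowMeans(E)              # zero between-practice variance
  Y <- outer(0.8 * x1, rep(1, Tm)) + E
  panel <- panel_from_matrix(Y, loc, covars = data.frame(x1 = x1))
  fit <- fit_random_intercept(panel,
                              mixed_model_spec("x1",
                                               offset = rep(0, Tm)))
  expect_lt(fit$sigma_b2, 1e-6 * fit$sigma_e2)
  ols <- lm(log_rate ~ x1, data = panel$records)
  expect_equal(fit$coefficients$estimate, as.numeric(coef(ols)),
               tolerance = 1e-6)
})

test_that("the offset contract holds: a common shift of offset and
           outcome changes nothing and its coefficient is exactly 1", {
  sim <- small_sim(seed = 25)
  sp <- mixed_model_spec(c("income", "age"), offset = sim$truth$mu_t)
  fit1 <- fit_random_intercept(sim$panel, sp)
  shifted <- sim$panel
  shifted$records$log_rate <- shifted$records$log_rate + 5
  sp2 <- mixed_model_spec(c("income", "age"),
                          offset = sim$truth$mu_t + 5)
  fit2 <- fit_random_intercept(shifted, sp2)
  # identities hold to the one-dimensional optimiser's precision
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-5)
  expect_equal(fit1$sigma_b2, fit2$sigma_b2, tolerance = 1e-5)
  # doubling the offset is NOT absorbed (coefficient pinned at 1)
  sp3 <- mixed_model_spec(c("income", "age"),
                          offset = 2 * sim$truth$mu_t)
  fit3 <- fit_random_intercept(sim$panel, sp3)
  expect_false(isTRUE(all.equal(fit1$coefficients$estimate,
                                fit3$coefficients$estimate)))
})

test_that("the REML criterion value is invariant to a full-rank
           reparameterisation of the fixed effects", {
  sim <- small_sim(seed = 26)
  sp <- mixed_model_spec(c("income", "age"), offset = sim$truth$mu_t)
  fit1 <- fit_random_intercept(sim$panel, sp)
  # reparameterise: replace income by a linear mix of income and age
  rep_panel <- sim$panel
  rep_panel$records$income <- 2 * rep_panel$records$income -
    0.3 * rep_panel$records$age
  fit2 <- fit_random_intercept(rep_panel, sp)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-6)
  expect_equal(fit1$sigma_b2, fit2$sigma_b2, tolerance = 1e-4)
  expect_equal(fit1$sigma_e2, fit2$sigma_e2, tolerance = 1e-4)
})

test_that("rank deficiency and missing offsets are rejected with
           informative errors", {
  sim <- small_sim(seed = 27)
  dup <- sim$panel
  dup$records$income2 <- dup$records$income
  dup$covariates <- c(dup$covariates, "income2")
  expect_error(
    fit_random_intercept(dup, mixed_model_spec(c("income", "income2"),
                                               offset = sim$truth$mu_t)),
    "collinear.*income2")
  expect_error(
    fit_random_intercept(sim$panel,
                         mixed_model_spec("income",
                                          offset = sim$truth$mu_t[1:5])),
    "offset")
})

test_that("BLUP intervals are sorted by conditional mean and shrink to
           zero when the practice variance vanishes", {
  sim <- small_sim(seed = 28)
  sp <- mixed_model_spec(c("income", "age"), offset = sim$truth$mu_t)
  fit <- fit_random_intercept(sim$panel, sp)
  bi <- blup_intervals(fit)
  expect_true(!is.unsorted(bi$blup))
  expect_true(all(bi$lower <= bi$blup & bi$blup <= bi$upper))
  # force the boundary: no practice effects in the data
  set.seed(29)
  loc <- gen_locations(6, seed = 4)
  Y <- matrix(rnorm(6 * 40, sd = 0.2), 6, 40)
  Y <- Y - rowMeans(Y)              # no between-practice variance
  p0 <- panel_from_matrix(Y, loc)
  f0 <- fit_random_intercept(p0, mixed_model_spec(character(),
                                                  offset = rep(0, 40)))
  expect_true(f0$boundary)
  expect_equal(blup_intervals(f0)$blup, rep(0, 6))
})

test_that("with many observations a practice's BLUP approaches its mean
           offset-adjusted residual", {
  set.seed(30)
  n <- 3L; Tm <- 10000L
  loc <- gen_locations(n, seed = 5)
  b <- c(0.5, -0.2, 0.1)
  Y <- outer(b, rep(1, Tm)) + matrix(rnorm(n * Tm, sd = 0.3), n, Tm)
  panel <- panel_from_matrix(Y, loc)
  fit <- fit_random_intercept(
    panel, mixed_model_spec(character(), offset = rep(0, Tm)))
  rec <- panel$records
  gm <- tapply(rec$log_rate - fit$coefficients$estimate[1],
               rec$practice_id, mean)
  bl <- fit$blups$blup[match(names(gm), fit$blups$practice_id)]
  expect_lt(max(abs(bl - as.numeric(gm)) / pmax(abs(gm), 0.1)), 0.01)
})

test_that("residual diagnostics report a unit lag-0 ACF for every
           practice and centred binned residuals", {
  sim <- small_sim(seed = 31, n = 10L, Tm = 40L)
  sp <- mixed_model_spec(c("income", "age"), offset = sim$truth$mu_t)
  fit <- fit_random_intercept(sim$panel, sp)
  rc <- residual_checks(fit)
  expect_true(all(abs(rc$acf_by_practice["lag0", ] - 1) < 1e-12))
  # correctly specified fit: binned residual means are small
  expect_true(all(abs(rc$binned$mean) <= 4 * rc$binned$se))
  expect_equal(nrow(rc$qq), fit$n)
})
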