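# Correlation diagnostics: ACF, semivariance cloud, binned variogram,
# trend-surface detrending, permutation envelope, ST variogram.

test_that("the ACF is 1 at lag 0 and tracks known serial dependence", {
  set.seed(41)
  x <- rnorm(500)
  a <- residual_acf(x, 12)
  expect_identical(a[1], 1)
  expect_true(mean(abs(a[-1]) < 3 / sqrt(500)) >= 10 / 12)
  # AR(1) with coefficient 0.8
  e <- rnorm(2000)
  ar <- as.numeric(stats::filter(e, 0.8, method = "recursive"))
  expect_lt(abs(residual_acf(ar, 1)[2] - 0.8), 0.05)
  expect_error(residual_acf(rep(2, 10), 3), "constant")
  expect_error(residual_acf(1:5, 5), "max_lag")
})

test_that("semivariances follow the half-squared-difference formula on
           hand-checkable pairs", {
  loc <- data.frame(easting = c(0, 3000), northing = c(0, 4000))
  cl <- semivariance_cloud(c(1, 3), loc)
  expect_equal(cl$dist, 5000)             # 3-4-5 triangle
  expect_equal(cl$semiv, 2.0)             # 0.5 * (1-3)^2
  loc4 <- data.frame(easting = runif(4), northing = runif(4))
  expect_equal(nrow(semivariance_cloud(rnorm(4), loc4)), 6L)  # C(4,2)
  expect_equal(semivariance_cloud(c(5, 5), loc)$semiv, 0)
  expect_error(semivariance_cloud(1:3, loc), "lengths differ")
})

test_that("the all-pairs mean semivariance equals the sample variance", {
  set.seed(42)
  v <- rnorm(40)
  loc <- data.frame(easting = runif(40, 0, 100),
                    northing = runif(40, 0, 100))
  cl <- semivariance_cloud(v, loc)
  expect_equal(mean(cl$semiv), var(v), tolerance = 1e-10)
})

test_that("binned variogram means equal brute-force enumeration and
           empty bins stay NA", {
  loc <- data.frame(easting = c(0, 500, 5200), northing = c(0, 0, 0))
  v <- c(1, 2, 4)
  cl <- semivariance_cloud(v, loc)
  bv <- binned_variogram(cl, breaks = seq(0, 6000, 1000))
  oracle <- oracle_binned_variogram(v, loc$easting, loc$northing,
                                    seq(0, 6000, 1000))
  expect_equal(bv$semiv, oracle)
  expect_true(is.na(bv$semiv[2]))         # no pair at [1,2) km
  expect_equal(sum(bv$n), 3L)
  # pairs beyond the maximum distance are discarded and counted
  bv2 <- binned_variogram(cl, breaks = seq(0, 5000, 1000))
  expect_equal(attr(bv2, "n_discarded"), 1L)   # only the 5.2 km pair
  expect_equal(sum(bv2$n), 2L)
})

test_that("for iid values every occupied bin sits near the sill (the
           process variance)", {
  set.seed(43)
  loc <- data.frame(easting = runif(200, 0, 20000),
                    northing = runif(200, 0, 20000))
  v <- rnorm(200)
  bv <- binned_variogram(semivariance_cloud(v, loc))
  occ <- bv[bv$n >= 50, ]
  expect_true(all(abs(occ$semiv - 1) < 0.35))
  # and the binned slope over distance is tiny across replicates
  slopes <- sapply(1:20, function(r) {
    set.seed(100 + r)
    vv <- rnorm(63)
    ll <- gen_locations(63, 20000, seed = 500 + r)
    b <- binned_variogram(semivariance_cloud(vv, ll))
    ok <- b$n > 0
    coef(lm(b$semiv[ok] ~ b$mid[ok]))[2]
  })
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(20)), 3)
})

test_that("trend-surface residuals annihilate planar fields and satisfy
           the normal equations", {
  loc <- data.frame(easting = runif(30, 0, 100),
                    northing = runif(30, 0, 100))
  planar <- 2 + 0.5 * loc$easting - 0.1 * loc$northing
  expect_lt(max(abs(trend_surface_residuals(planar, loc))), 1e-10)
  set.seed(44)
  v <- rnorm(30)
  r <- trend_surface_residuals(v, loc)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * loc$easting)), 1e-6)
  expect_lt(abs(sum(r * loc$northing)), 1e-6)
  expect_equal(r, as.numeric(v - cbind(1, loc$easting, loc$northing) %*%
                               oracle_ols(cbind(1, loc$easting,
                                                loc$northing), v)),
               tolerance = 1e-8)
  colin <- data.frame(easting = 1:10, northing = 2 * (1:10))
  expect_error(trend_surface_residuals(rnorm(10), colin), "collinear")
})

test_that("the permutation envelope is seed-deterministic, bounded, and
           its observed curve is order-invariant", {
  set.seed(45)
  loc <- gen_locations(30, 20000, seed = 6)
  v <- rnorm(30)
  e1 <- permutation_envelope(v, loc, n_perm = 29, seed = 9)
  e2 <- permutation_envelope(v, loc, n_perm = 29, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(e1$lower <= e1$upper))
  # joint relabeling of sites leaves the observed variogram unchanged
  ix <- sample(30)
  e3 <- permutation_envelope(v[ix], loc[ix, ], n_perm = 29, seed = 10)
  expect_equal(e1$observed, e3$observed, tolerance = 1e-12)
  expect_error(permutation_envelope(rnorm(5), loc[1:5, ]), "10 sites")
})

test_that("strong spatial correlation pushes short-range bins outside
           the envelope", {
  hits <- 0L
  for (r in 1:15) {
    loc <- gen_locations(63, 20000, seed = 700 + r)
    D <- as.matrix(dist(loc[, c("easting", "northing")]))
    set.seed(800 + r)
    v <- drop(crossprod(chol(exp(-D / 10000) + diag(1e-8, 63)),
                        rnorm(63)))
    env <- permutation_envelope(v, loc, n_perm = 99, seed = 900 + r)
    short <- env[env$mid <= 5000 & !is.na(env$observed), ]
    if (any(!short$inside)) hits <- hits + 1L
  }
  expect_gte(hits, 13L)   # >= ~90% power at this correlation range
})

test_that("the ST variogram's lag-0 column is the contemporaneous
           spatial variogram, and same-site pairs enter only at
           positive lags", {
  sim <- small_sim(seed = 46, n = 12L, Tm = 20L)
  rec <- sim$panel$records
  rec$residual <- as.numeric(sim$truth$eps[cbind(
    match(rec$practice_id, sim$panel$locations$practice_id),
    rec$month)])
  stv <- st_variogram(rec, sim$panel$locations, max_lag = 2)
  # oracle for lag 0: pool contemporaneous pairs across months
  loc <- sim$panel$locations
  sums <- cnt <- rep(0, 20)
  for (t in 1:20) {
    vt <- rec$residual[rec$month == t][match(loc$practice_id,
                                             rec$practice_id[rec$month == t])]
    cl <- semivariance_cloud(vt, loc)
    b <- findInterval(cl$dist, seq(0, 20000, 1000))
    ok <- b >= 1 & b <= 20
    agg <- rowsum(cl$semiv[ok], b[ok])
    sums[as.integer(rownames(agg))] <- sums[as.integer(rownames(agg))] +
      agg[, 1]
    cnt <- cnt + tabulate(b[ok], 20)
  }
  oracle_lag0 <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA)
  expect_equal(as.numeric(stv$semiv[, "lag0"]), oracle_lag0,
               tolerance = 1e-10)
  # at lag 1, the zero-distance bin holds the same-site pairs
  expect_gte(stv$n[1, "lag1"], 12 * 19)
  expect_equal(stv$n[1, "lag0"], 0)     # no same-site pairs at lag 0
  expect_lte(sum(stv$n[, "lag0"]), 20 * choose(12, 2))
})

test_that("separable spatiotemporal residuals produce semivariance
           rising in both distance and time lag", {
  ok_dist <- ok_lag <- 0L
  for (r in 1:8) {
    sim <- gen_panel(panel_gen_config(
      seed = 1000 + r, resid_type = "spatiotemporal",
      spatial_range_m = 8000, ar_coef = 0.7))
    rec <- sim$panel$records
    rec$residual <- as.numeric(sim$truth$eps[cbind(
      match(rec$practice_id, sim$panel$locations$practice_id),
      rec$month)])
    stv <- st_variogram(rec, sim$panel$locations, max_lag = 3)
    cell <- expand.grid(d = stv$dist_mid, h = stv$lags)
    sv <- as.numeric(stv$semiv)
    use <- !is.na(sv) & as.numeric(stv$n) > 30
    if (cor(sv[use], cell$d[use], method = "spearman") > 0)
      ok_dist <- ok_dist + 1L
    if (cor(sv[use], cell$h[use], method = "spearman") > 0)
      ok_lag <- ok_lag + 1L
  }
  expect_gte(ok_dist, 7L)
  expect_gte(ok_lag, 7L)
})
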