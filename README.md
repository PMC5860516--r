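# dhrpanel

Two-stage modelling of seasonally varying, spatially indexed health
time series — for epidemiologists and health-services analysts working
with panels such as monthly prescribing rates from a network of
primary-care practices, where every unit shares a strong seasonal
signal (winter/spring peaks whose size and shape drift between years)
and the question of interest lives in the unit-level, spatiotemporal
remainder.

## The method

**Stage one** fits the area-wide monthly log rate with a *dynamic
harmonic regression* (DHR), a Gaussian state-space model

```
Y(t) = a + β d(t) + Σ_{p=1..k} { A_{p,t} cos(pωt) + B_{p,t} sin(pωt) } + U_t,
ω = 2π/12,
```

where `d(t)` is lagged monthly mean temperature and the harmonic
coefficients `A_{p,t}, B_{p,t}` evolve as random walks.  The model is
fitted by maximum likelihood through the Kalman filter
(prediction-error decomposition), smoothed to obtain the area-wide
seasonal curve `μ̂_t`, and compared against the static (OLS) harmonic
regression.  The temperature lag (0, 7, 14, 21 days or one month) is
selected by the squared correlation between observed and fitted values.

**Stage two** fits the practice-level panel with a random-intercept
linear mixed model in which `μ̂_t` enters as an offset (coefficient
fixed at 1):

```
y_jt = μ̂_t + x_jt' a + b_j + ε_jt,   b_j ~ N(0, σ_b²),  ε_jt ~ N(0, σ_ε²),
```

estimated by profiled REML (or ML): closed-form GLS fixed effects given
the variance ratio, one-dimensional search on its log.  Practice
effects come out as BLUPs with prediction intervals.

**Diagnostics** then check what is left: residual autocorrelation
functions, the empirical semivariance `v_ij = ½(y_i − y_j)²` binned by
distance with a 99-permutation envelope after OLS trend-surface
detrending, and the spatiotemporal variogram over distance × time-lag
cells (1-km bins to 20 km, lags 0–3 months).

A seeded synthetic-panel generator (`gen_panel()`) reproduces the
structure all of this assumes — drifting seasonality, a shared lagged
temperature driver, covariates, practice random intercepts, optional
spatially or spatiotemporally correlated residuals — and always emits
the ground truth next to the panel, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(dhrpanel)

sim  <- gen_panel(panel_gen_config(seed = 1))   # 63 practices x 55 months
area <- area_average(sim$panel)                 # area-wide monthly series

sel <- select_lag(area, sim$daily_temp, dhr_spec(k = 2))
sel
#> Temperature lag selection (squared correlation of fit):
#>  lag     r2 loglik converged
#>   0d 0.9976  84.45      TRUE
#>   7d 0.9979  88.95      TRUE
#>  14d 0.9965  86.04      TRUE
#>  21d 0.9965  85.73      TRUE
#>   1m 0.9968  85.17      TRUE
#> Best lag: 7d
```

The generator drives prescribing with temperature at a 7-day lag, and
the lag search recovers it; the dynamic fit statistic at the selected
lag (0.998) exceeds the static harmonic regression's on the same data.
The smoothed curve of the winning fit then becomes the stage-two
offset:

```r
fit <- fit_random_intercept(
  sim$panel,
  mixed_model_spec(c("air_pollution", "income", "employment", "age",
                     "time_elapsed"), offset = sel$best_fit))
fit
#> Random-intercept mixed model (REML), 3465 records, 63 practices
#>           term   estimate        se  t_value  p_value
#>    (Intercept) -2.238e+00 0.2964081 -7.55003 5.53e-14
#>  air_pollution  3.340e-04 0.0004655  0.71750    0.473
#>         income  1.923e+00 0.2874710  6.69067 2.58e-11
#>     employment  1.899e+00 0.2989265  6.35259 2.39e-10
#>            age  3.653e-02 0.0081843  4.46307 8.34e-06
#>  time_elapsed  5.138e-06 0.0001059  0.04852    0.961
#>   sigma_b^2 = 0.011642, sigma_eps^2 = 0.0097725
```

Income and employment deprivation and patient age come out as strong
positive predictors (the generator's true effects are 1.8, 2.3 and
0.03 on these scales); the area-wide covariates (air pollution, elapsed
time) are largely absorbed by the offset, which already tracks the
area-wide mean.  `blup_intervals(fit)` returns the practice effects
with 95% prediction intervals, sorted for the caterpillar plot, and
`permutation_envelope()` / `st_variogram()` on the results show — for
iid-residual panels — a variogram inside the envelope and a flat
distance × lag surface: no residual spatiotemporal correlation to
model.

`run_pipeline(run_config(sim_config = panel_gen_config(), seed = 1))`
chains all of the above and writes every table plus a JSON summary to
an output directory; `inst/cli/dhrpanel` wraps the same functions as
`simulate` / `fit-dhr` / `fit-mixed` / `diagnose` / `run` subcommands.

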