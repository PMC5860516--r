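# Temporal, spatial and spatiotemporal correlation diagnostics.

#' Sample autocorrelation function
#'
#' Standard sample autocorrelations with the single-overall-mean,
#' lag-0-variance normalisation (the convention of [stats::acf]), so
#' the lag-0 value is exactly 1.
#'
#' @param x ordered numeric vector (one series).
#' @param max_lag maximum lag, `0 <= max_lag < length(x)`.
#' @return numeric vector of autocorrelations at lags `0..max_lag`.
#' @export
residual_acf <- function(x, max_lag = 12L) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in series")
  if (max_lag < 0L || length(x) <= max_lag)
    stop("need length(x) > max_lag >= 0")
  if (sd(x) == 0)
    stop("undefined statistic: constant series has no autocorrelation")
  out <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
  out[1L] <- 1   # exact by definition; clear eps-level roundoff
  out
}

#' Semivariance cloud
#'
#' All unordered pairs of observations with their planar Euclidean
#' distance, absolute time difference (when times are supplied) and
#' semivariance \eqn{v_{ij} = \frac{1}{2}(y_i - y_j)^2}.
#'
#' @param values numeric vector of observations.
#' @param locations data frame or matrix with columns `easting` and
#'   `northing` (metres), one row per observation.
#' @param times optional integer vector of observation times (months).
#' @return data frame of class `semivariance_cloud` with columns `i`,
#'   `j`, `dist`, `tdiff` (0 when no times given), `semiv`.
#' @export
semivariance_cloud <- function(values, locations, times = NULL) {
  n <- length(values)
  loc <- as.matrix(as.data.frame(locations)[, c("easting", "northing")])
  if (nrow(loc) != n)
    stop("invalid argument: `values` and `locations` lengths differ")
  if (!is.null(times) && length(times) != n)
    stop("invalid argument: `times` length differs from `values`")
  if (n < 2L) stop("need at least 2 observations")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d <- sqrt((loc[i, 1L] - loc[j, 1L])^2 + (loc[i, 2L] - loc[j, 2L])^2)
  td <- if (is.null(times)) rep(0L, length(i)) else abs(times[i] - times[j])
  out <- data.frame(i = i, j = j, dist = d, tdiff = td,
                    semiv = 0.5 * (values[i] - values[j])^2)
  class(out) <- c("semivariance_cloud", "data.frame")
  out
}

#' Binned empirical variogram
#'
#' Mean semivariance per distance bin.  Bins are left-closed,
#' right-open; pairs at or beyond `max_dist` are discarded and the
#' discard count reported.  Empty bins carry `NA` means (never zero).
#'
#' @param cloud a [semivariance_cloud] (or data frame with `dist` and
#'   `semiv`).
#' @param breaks distance bin edges in metres (default 1-km bins to
#'   20 km).
#' @param max_dist maximum distance retained, metres.
#' @return object of class `variogram_estimate`: data frame with
#'   `lower`, `upper`, `mid`, `n`, `semiv`; attribute `n_discarded`.
#' @export
binned_variogram <- function(cloud, breaks = seq(0, 20000, by = 1000),
                             max_dist = max(breaks)) {
  breaks <- sort(breaks)
  keep <- cloud$dist < max_dist
  n_disc <- sum(!keep)
  cl <- cloud[keep, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no pairs within `max_dist`")
  bin <- findInterval(cl$dist, breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  nb <- length(breaks) - 1L
  bin[bin < 1L | bin > nb] <- NA
  cnt <- tabulate(bin, nbins = nb)
  sums <- rep(0, nb)
  ok <- !is.na(bin)
  if (any(ok)) {
    agg <- rowsum(cl$semiv[ok], bin[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
                    mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    n = cnt,
                    semiv = ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_))
  attr(out, "n_discarded") <- n_disc
  class(out) <- c("variogram_estimate", "data.frame")
  out
}

#' Residuals from an OLS linear trend surface
#'
#' Ordinary-least-squares residuals of `value ~ 1 + easting +
#' northing`, the detrending step applied before permutation envelopes.
#'
#' @param values numeric vector.
#' @param locations data frame with `easting` and `northing`.
#' @return numeric vector of residuals.
#' @export
trend_surface_residuals <- function(values, locations) {
  loc <- as.data.frame(locations)
  if (length(values) < 4L) stop("need at least 4 sites")
  X <- cbind(1, loc$easting, loc$northing)
  if (qr(X)$rank < 3L)
    stop("collinear site coordinates: trend surface is not identifiable")
  as.numeric(resid(lm(values ~ easting + northing, data =
                        cbind(loc, values = values))))
}

#' Permutation envelope for the empirical variogram
#'
#' Detrends the values with an OLS linear trend surface, computes the
#' binned variogram of the residuals, then recomputes it for each of
#' `n_perm` seeded random permutations of the residuals over the
#' locations.  The envelope is the pointwise minimum and maximum across
#' permutations; an observed variogram inside the envelope everywhere
#' is consistent with no spatial correlation.
#'
#' @param values numeric vector, one value per site (e.g. practice-level
#'   random-effect estimates).
#' @param locations data frame with `easting` and `northing`.
#' @param n_perm number of permutations (default 99, giving a pointwise
#'   two-sided exceedance probability of about 2/100 per bin).
#' @param seed integer RNG seed; recorded in the result.
#' @param breaks distance bin edges, metres.
#' @param max_dist maximum distance retained.
#' @return object of class `envelope_result`: data frame with `mid`,
#'   `n`, `observed`, `lower`, `upper`, `inside`; attributes `n_perm`
#'   and `seed`.
#' @export
permutation_envelope <- function(values, locations, n_perm = 99L,
                                 seed = NULL,
                                 breaks = seq(0, 20000, by = 1000),
                                 max_dist = max(breaks)) {
  n <- length(values)
  if (n < 10L) stop("need at least 10 sites for a meaningful envelope")
  z <- trend_surface_residuals(values, locations)
  loc <- as.data.frame(locations)
  cloud <- semivariance_cloud(z, loc)
  obs <- binned_variogram(cloud, breaks, max_dist)
  i <- cloud$i; j <- cloud$j
  # distances (hence bin memberships) are fixed across permutations
  bin <- findInterval(cloud$dist, breaks)
  nb <- length(breaks) - 1L
  valid <- cloud$dist < max_dist & bin >= 1L & bin <= nb
  binv <- bin[valid]
  cnt <- tabulate(binv, nbins = nb)
  perm_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(s) {
      zp <- z[sample.int(n)]
      sv <- 0.5 * (zp[i[valid]] - zp[j[valid]])^2
      sums <- rep(0, nb)
      agg <- rowsum(sv, binv)
      sums[as.integer(rownames(agg))] <- agg[, 1L]
      ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)
    }, numeric(nb))
  })
  lower <- apply(perm_mat, 1L, min)
  upper <- apply(perm_mat, 1L, max)
  out <- data.frame(mid = obs$mid, n = obs$n, observed = obs$semiv,
                    lower = lower, upper = upper)
  out$inside <- is.na(out$observed) |
    (out$observed >= out$lower & out$observed <= out$upper)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("envelope_result", "data.frame")
  out
}

#' @export
print.envelope_result <- function(x, ...) {
  occ <- x[!is.na(x$observed), ]
  cat(sprintf(
    "Variogram permutation envelope (%d permutations): %d/%d bins inside\n",
    attr(x, "n_perm"), sum(occ$inside), nrow(occ)))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spatiotemporal empirical variogram
#'
#' Mean semivariance in cells of spatial distance bin by temporal lag,
#' for residuals indexed by practice and month.  The lag-0 column uses
#' contemporaneous cross-practice pairs only; at positive lags,
#' same-practice pairs contribute to the zero-distance bin.
#'
#' @param residuals data frame with `practice_id`, `month` and a value
#'   column (default `residual`).
#' @param locations data frame with `practice_id`, `easting`,
#'   `northing`.
#' @param breaks distance bin edges, metres (default 1-km bins to
#'   20 km).
#' @param max_lag maximum time lag in months (default 3).
#' @param value name of the value column.
#' @return object of class `st_variogram`: list with matrices `semiv`
#'   and `n` (distance bin x time lag) and the bin midpoints/lags.
#' @export
st_variogram <- function(residuals, locations,
                         breaks = seq(0, 20000, by = 1000),
                         max_lag = 3L, value = "residual") {
  stopifnot(all(c("practice_id", "month", value) %in% names(residuals)))
  ids <- locations$practice_id
  n <- length(ids)
  months <- sort(unique(residuals$month))
  Y <- matrix(NA_real_, n, max(months),
              dimnames = list(ids, NULL))
  Y[cbind(match(residuals$practice_id, ids), residuals$month)] <-
    residuals[[value]]
  D <- as.matrix(dist(locations[, c("easting", "northing")]))
  nb <- length(breaks) - 1L
  binm <- matrix(findInterval(D, breaks), n, n)
  binm[binm < 1L | binm > nb] <- NA     # beyond last edge: discarded
  lags <- 0:max_lag
  semiv <- cnt <- matrix(0, nb, length(lags),
                         dimnames = list(paste0("d", seq_len(nb)),
                                         paste0("lag", lags)))
  up <- upper.tri(D)
  for (h in lags) {
    col <- h + 1L
    for (t in months) {
      if (h > 0L && !((t + h) %in% months)) next
      y1 <- Y[, t]
      y2 <- Y[, t + h]
      V <- 0.5 * (outer(y1, y2, "-"))^2
      use <- if (h == 0L) up else matrix(TRUE, n, n)
      ok <- use & !is.na(V) & !is.na(binm)
      if (!any(ok)) next
      b <- binm[ok]
      agg <- rowsum(V[ok], b)
      ii <- as.integer(rownames(agg))
      semiv[ii, col] <- semiv[ii, col] + agg[, 1L]
      cnt[ii, col] <- cnt[ii, col] + tabulate(b, nbins = nb)[ii]
    }
  }
  mean_sv <- ifelse(cnt > 0, semiv / pmax(cnt, 1), NA_real_)
  structure(list(semiv = mean_sv, n = cnt,
                 dist_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                 lags = lags),
            class = "st_variogram")
}

#' @export
print.st_variogram <- function(x, ...) {
  cat("Spatiotemporal empirical variogram (mean semivariance):\n")
  m <- round(x$semiv, 4)
  rownames(m) <- sprintf("%.1f km", x$dist_mid / 1000)
  print(m)
  invisible(x)
}
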