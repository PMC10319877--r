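#' @title Movement statistics: velocity distributions, MSD, autocorrelation
#' @name movement-stats
#' @description
#' Three cohort-level statistics characterize the movement and are used to
#' check that interpolation does not distort the data: the probability
#' density of the instantaneous velocity `v` (and of the log-normalized
#' velocity `u = ln(v / v_m)`, with `v_m` the trip's mean instantaneous
#' velocity), the mean squared displacement
#' `MSD(tau) = E[|r(t + tau) - r(t)|^2]`, and the autocorrelation of `u`,
#' `C(tau) = E[(u(t+tau) - u_m)(u(t) - u_m)] / E[(u(t) - u_m)^2]`. Both
#' curves average over all time origins within a trip and then over trips
#' with equal weight; confidence intervals are bootstrap-over-trips.
NULL

#' Log-normalized velocity series
#'
#' `u = ln(v / v_m)`; steps with `v = 0` are excluded (ln 0 undefined) and
#' counted.
#'
#' @param v Instantaneous velocity vector (m/s); `NA`s allowed.
#' @param v_m Normalizing mean velocity; defaults to `mean(v)` over all
#'   finite steps (zeros included in the mean, as `v_m = E[v(t)]`).
#' @return List: `u` (same length as `v`, `NA` where `v` is 0 or missing),
#'   `v_m`, `n_zero`.
#' @export
log_velocity <- function(v, v_m = NULL) {
  fin <- is.finite(v)
  if (!any(fin) || all(v[fin] == 0)) abort("all velocities are zero or missing")
  if (is.null(v_m)) v_m <- mean(v[fin])
  u <- ifelse(fin & v > 0, log(v / v_m), NA_real_)
  list(u = u, v_m = v_m, n_zero = sum(fin & v == 0))
}

.track_u <- function(track) {
  if (!"v" %in% names(track)) track <- add_steps(track)
  v <- track$v[seq_len(nrow(track) - 1)]
  log_velocity(v)$u
}

#' Mean squared displacement of a cohort
#'
#' For each lag `tau` (in seconds, on uniformly 1 Hz tracks) the squared
#' great-circle displacement is averaged over all time origins within each
#' trip, then across trips with equal weight. The 95% confidence band is a
#' bootstrap over trips.
#'
#' @param cohort Cohort tibble of uniformly sampled (interpolated) tracks.
#' @param max_lag Largest lag in seconds; lags beyond a trip's span are
#'   truncated for that trip.
#' @param n_boot Bootstrap resamples over trips.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return An `msd_curve` tibble: `lag`, `msd` (m^2), `ci_low`, `ci_high`,
#'   `n_tracks`, `n_pairs`.
#' @export
cohort_msd <- function(cohort, max_lag = 100, n_boot = 500, conf = 0.95,
                       seed = NULL) {
  per_track <- purrr::map(cohort$track, function(tr) {
    n <- nrow(tr)
    lags <- seq_len(min(max_lag, n - 1))
    vals <- rep(NA_real_, max_lag)
    npairs <- rep(0L, max_lag)
    for (tau in lags) {
      i <- seq_len(n - tau)
      d <- haversine_m(tr$latitude[i], tr$longitude[i],
                       tr$latitude[i + tau], tr$longitude[i + tau])
      vals[tau] <- mean(d^2)
      npairs[tau] <- length(i)
    }
    list(vals = vals, npairs = npairs)
  })
  mat <- do.call(rbind, purrr::map(per_track, "vals"))
  npairs <- colSums(do.call(rbind, purrr::map(per_track, "npairs")))
  msd <- colMeans(mat, na.rm = TRUE)
  ci <- .boot_ci(mat, n_boot = n_boot, conf = conf, seed = seed)
  out <- tibble(lag = c(0, seq_len(max_lag)),
                msd = c(0, msd),
                ci_low = c(0, ci[1, ]), ci_high = c(0, ci[2, ]),
                n_tracks = c(nrow(mat), colSums(!is.na(mat))),
                n_pairs = c(sum(npairs), npairs))
  class(out) <- c("msd_curve", class(out))
  out
}

#' Autocorrelation of the log-normalized velocity
#'
#' Per trip, the autocovariance of `u` at lag `tau` over all complete pairs,
#' normalized by the trip's lag-0 variance, then averaged over trips.
#' `C(0) = 1` by construction. Trips with zero variance in `u` are skipped
#' with a message.
#'
#' @inheritParams cohort_msd
#' @return A `vacf_curve` tibble: `lag`, `c`, `ci_low`, `ci_high`,
#'   `n_tracks`.
#' @export
cohort_vacf <- function(cohort, max_lag = 60, n_boot = 500, conf = 0.95,
                        seed = NULL) {
  rows <- purrr::map(cohort$track, function(tr) {
    u <- .track_u(tr)
    u_m <- mean(u, na.rm = TRUE)
    dev <- u - u_m
    v0 <- mean(dev^2, na.rm = TRUE)
    if (!is.finite(v0) || v0 == 0) return(NULL)
    n <- length(dev)
    vals <- rep(NA_real_, max_lag + 1)
    vals[1] <- 1
    for (tau in seq_len(min(max_lag, n - 1))) {
      prod <- dev[seq_len(n - tau)] * dev[seq_len(n - tau) + tau]
      if (any(is.finite(prod))) vals[tau + 1] <- mean(prod, na.rm = TRUE) / v0
    }
    vals
  })
  skipped <- sum(purrr::map_lgl(rows, is.null))
  if (skipped > 0) inform(paste0(skipped, " trip(s) with zero log-velocity variance skipped"))
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("no trips with usable log-velocity series")
  mat <- do.call(rbind, rows)
  cc <- colMeans(mat, na.rm = TRUE)
  ci <- .boot_ci(mat, n_boot = n_boot, conf = conf, seed = seed)
  out <- tibble(lag = 0:max_lag, c = cc,
                ci_low = ci[1, ], ci_high = ci[2, ],
                n_tracks = colSums(!is.na(mat)))
  class(out) <- c("vacf_curve", class(out))
  out
}

# bootstrap-over-rows CI of column means
.boot_ci <- function(mat, n_boot, conf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(mat)
  alpha <- (1 - conf) / 2
  boots <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nr, nr, replace = TRUE)
    boots[b, ] <- colMeans(mat[idx, , drop = FALSE], na.rm = TRUE)
  }
  apply(boots, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
}

#' Pooled velocity histogram of a cohort
#'
#' Instantaneous velocities binned at 0.1 m/s on `[0, 9]`, or log-normalized
#' velocities binned at 0.1 on `[-5, 2]`, as empirical densities.
#'
#' @param cohort Cohort tibble.
#' @param scale `"v"` (m/s) or `"u"` (log-normalized).
#' @param binwidth Bin width (default 0.1).
#' @return A `velocity_pdf` tibble: `bin_mid`, `density`, `n`.
#' @export
velocity_pdf <- function(cohort, scale = c("v", "u"), binwidth = 0.1) {
  scale <- match.arg(scale)
  vals <- unlist(purrr::map(cohort$track, function(tr) {
    if (scale == "v") {
      if (!"v" %in% names(tr)) tr <- add_steps(tr)
      tr$v
    } else {
      .track_u(tr)
    }
  }))
  vals <- vals[is.finite(vals)]
  rng <- if (scale == "v") c(0, 9) else c(-5, 2)
  breaks <- seq(rng[[1]], rng[[2]], by = binwidth)
  vals <- vals[vals >= rng[[1]] & vals <= rng[[2]]]
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  out <- tibble(bin_mid = h$mids, density = h$density, n = h$counts)
  attr(out, "scale") <- scale
  class(out) <- c("velocity_pdf", class(out))
  out
}

#' @method glance msd_curve
#' @export
glance.msd_curve <- function(x, ...) {
  tibble(max_lag = max(x$lag), msd_max = max(x$msd, na.rm = TRUE),
         n_tracks = max(x$n_tracks))
}

#' @method glance vacf_curve
#' @export
glance.vacf_curve <- function(x, ...) {
  tibble(max_lag = max(x$lag), c1 = x$c[x$lag == 1][1],
         n_tracks = max(x$n_tracks))
}
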