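#' @title Spatial k-anonymity geomasking and disclosure risk
#' @name geomask
#' @description
#' To protect home locations, each surviving trip has a random window of
#' movement stripped from its home-side end: the first `t` seconds of
#' movement for home-to-school trips, the last `t` seconds for
#' school-to-home trips, with `t` drawn uniformly on the integers 20..50 s.
#' The privacy gained is quantified by spatial k-anonymity: walking at an
#' assumed constant speed `v` for `t` seconds, the trip endpoint is
#' consistent with any of the `k = density * pi * (v t)^2` housing units
#' inside the circle of radius `d = v t`, so the disclosure risk — the
#' probability of guessing the true home — is `1/k`.
NULL

#' Geomasking parameters
#'
#' @param v_assumed Assumed constant walking speed in m/s (default 1.5).
#' @param t_min,t_max Bounds (s) of the uniform integer masking window
#'   (defaults 20 and 50).
#' @param rng_seed Optional integer seed used by [geomask_cohort()] for the
#'   per-trip draws.
#' @return A `geomask_policy` list.
#' @export
geomask_policy <- function(v_assumed = 1.5, t_min = 20, t_max = 50,
                           rng_seed = NULL) {
  if (v_assumed <= 0) abort("v_assumed must be positive")
  if (!(t_min > 0 && t_min <= t_max)) abort("need 0 < t_min <= t_max")
  structure(list(v_assumed = v_assumed, t_min = t_min, t_max = t_max,
                 rng_seed = rng_seed),
            class = "geomask_policy")
}

#' Housing density of a district
#'
#' @param housing_units Number of housing units.
#' @param surface_km2 Urban surface in square kilometers (> 0).
#' @return Density in units per square kilometer.
#' @examples
#' housing_density(74729, 6.105)  # 12240.62
#' @export
housing_density <- function(housing_units, surface_km2) {
  if (any(surface_km2 <= 0)) abort("surface must be positive")
  housing_units / surface_km2
}

#' Disclosure risk 1/k for a masked endpoint
#'
#' `k` is the number of housing units inside the circle of radius
#' `d = v_assumed * t` around the masked endpoint:
#' `k = density * pi * d^2`, with `d` converted to km. The risk is `1/k` and
#' is strictly decreasing in both the housing density and `t`.
#'
#' @param density Housing units per km^2 (> 0).
#' @param t Masked time in seconds (> 0).
#' @param policy A [geomask_policy()] (supplies `v_assumed`).
#' @return Disclosure risk `1/k` (vectorized over `density` and `t`).
#' @examples
#' disclosure_risk(12240.62, t = 50)  # ~4.62e-3
#' @export
disclosure_risk <- function(density, t, policy = geomask_policy()) {
  if (any(density <= 0)) abort("density must be positive: k would be zero and 1/k undefined")
  if (any(t <= 0)) abort("t must be positive: k would be zero and 1/k undefined")
  d_km <- policy$v_assumed * t / 1000
  k <- density * pi * d_km^2
  1 / k
}

#' District housing table
#'
#' The shipped table lists, per district (or city), the urban surface, the
#' number of housing units and the school codes located there; the housing
#' density and the disclosure risk at `t = 50` s are derived columns.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `district,surface_km2,housing_units,schools`.
#' @param policy A [geomask_policy()].
#' @param t Masking time (s) at which the reference risk column is computed.
#' @return A tibble with columns `district`, `surface_km2`, `housing_units`,
#'   `schools`, `density`, `risk`.
#' @export
district_housing <- function(path = NULL, policy = geomask_policy(), t = 50) {
  if (is.null(path)) {
    path <- system.file("extdata", "district_housing.csv", package = "pedtrack")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dat$density <- housing_density(dat$housing_units, dat$surface_km2)
  dat$risk <- disclosure_risk(dat$density, t = t, policy = policy)
  dat
}

#' Average disclosure risk over districts
#'
#' Unweighted arithmetic mean of the per-district risks.
#'
#' @param districts Tibble with `housing_units` and `surface_km2` (or a
#'   precomputed `density`) columns, e.g. [district_housing()].
#' @param t Masking time in seconds.
#' @param policy A [geomask_policy()].
#' @return Mean risk (scalar).
#' @examples
#' average_disclosure_risk(district_housing())  # ~2.72e-3
#' @export
average_disclosure_risk <- function(districts, t = 50,
                                    policy = geomask_policy()) {
  if (nrow(districts) == 0) abort("no districts supplied")
  density <- districts$density %||%
    housing_density(districts$housing_units, districts$surface_km2)
  mean(disclosure_risk(density, t = t, policy = policy))
}

# movement mask: a record participates in movement if either adjacent step
# has nonzero velocity
.moving_mask <- function(track) {
  if (!"v" %in% names(track)) track <- add_steps(track)
  n <- nrow(track)
  v_out <- track$v
  v_in <- c(NA_real_, v_out[-n])
  out_mv <- !is.na(v_out) & v_out > 0
  in_mv <- !is.na(v_in) & v_in > 0
  out_mv | in_mv
}

#' Mask the home-side end of one track
#'
#' For `home_to_school` trips all records within the first `t` seconds of
#' movement (counted from the first moving fix, and including any stationary
#' lead) are removed; for `school_to_home` trips the last `t` seconds. The
#' removed set is always a contiguous prefix or suffix.
#'
#' @param track Record tibble.
#' @param t Masking window in seconds.
#' @param direction `"home_to_school"` or `"school_to_home"`.
#' @return List: `track` (masked tibble), `n_removed`,
#'   `duration_removed` (elapsed seconds of movement stripped).
#' @export
mask_track <- function(track, t,
                       direction = c("home_to_school", "school_to_home")) {
  direction <- match.arg(direction)
  moving <- .moving_mask(track)
  if (!any(moving)) abort("track has no movement; cannot geomask")
  tsec <- as.numeric(track$time)
  if (direction == "home_to_school") {
    t0 <- tsec[which(moving)[1]]
    drop <- tsec < t0 + t
  } else {
    t1 <- tsec[tail(which(moving), 1)]
    drop <- tsec > t1 - t
  }
  kept <- track[!drop, , drop = FALSE]
  dur <- if (direction == "home_to_school") {
    min(c(tsec[!drop], t0 + t)) - t0
  } else {
    t1 - max(c(tsec[!drop], t1 - t))
  }
  list(track = kept, n_removed = sum(drop),
       duration_removed = min(dur, t))
}

#' Stage 4: geomask a cohort
#'
#' Draws one integer `t ~ U(t_min, t_max)` per trip (seeded via
#' `policy$rng_seed` when set) and applies [mask_track()] according to each
#' trip's direction. Trips left with fewer than `min_records` records are
#' discarded with a reason.
#'
#' @param cohort Cohort tibble with its `direction` column filled in (see
#'   [infer_direction()]).
#' @param policy A [geomask_policy()].
#' @param min_records Minimum surviving records.
#' @return List: `cohort` (masked trips, step columns recomputed),
#'   `mask_report` tibble (`id`, `t`, `n_removed`, `duration_removed`,
#'   `discarded`).
#' @export
geomask_cohort <- function(cohort, policy = geomask_policy(),
                           min_records = 30) {
  if (any(is.na(cohort$direction))) {
    abort("all trips need a direction before geomasking; see infer_direction()")
  }
  if (!is.null(policy$rng_seed)) set.seed(policy$rng_seed)
  t_draw <- sample(seq(policy$t_min, policy$t_max), nrow(cohort),
                   replace = TRUE)
  masked <- purrr::pmap(list(cohort$track, t_draw, cohort$direction),
                        function(tr, t, dir) mask_track(tr, t, dir))
  n_left <- purrr::map_int(masked, ~ nrow(.x$track))
  discard <- n_left < min_records
  report <- tibble(
    id = cohort$id,
    t = t_draw,
    n_removed = purrr::map_int(masked, "n_removed"),
    duration_removed = purrr::map_dbl(masked, "duration_removed"),
    discarded = discard
  )
  out <- cohort[!discard, , drop = FALSE]
  out$track <- purrr::map(masked[!discard], ~ add_steps(.x$track))
  out$n_records <- purrr::map_int(out$track, nrow)
  list(cohort = out, mask_report = report)
}
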