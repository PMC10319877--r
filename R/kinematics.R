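#' @title Kinematic featurization on the time-advanced convention
#' @name kinematics
#' @description
#' Step quantities are defined time-advanced: the interval `dt(t)`, the
#' distance `d(t) = |r(t + dt) - r(t)|` and the instantaneous velocity
#' `v(t) = d(t) / dt(t)` at row `i` refer to the interval between fixes `i`
#' and `i + 1`, so the last row carries no step values. Trip-level summaries
#' are the total distance `D = sum d(t)`, the duration `T = sum dt(t)`, the
#' effective speed `v_eff = D / T`, and the mean instantaneous velocity
#' `v_m = E[v(t)]` used to normalize log-velocities.
NULL

# mean Earth radius (m); haversine at <10 km scale differs from a full
# geodesic by far less than the 6-dp coordinate rounding of the files
.earth_radius_m <- 6371008.8

#' Great-circle distance between WGS84 coordinates
#'
#' Haversine distance with mean Earth radius 6,371,008.8 m, vectorized over
#' its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in meters.
#' @examples
#' haversine_m(0, 0, 0.001, 0)  # ~111.19 m
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = .earth_radius_m))
}

#' Attach time-advanced step columns to a track
#'
#' Adds (or recomputes) the `dt`, `d` and `v` columns. With fewer than two
#' records the columns are attached as `NA` with a warning.
#'
#' @param track Record tibble with `time`, `latitude`, `longitude`.
#' @return The track with `dt` (s), `d` (m) and `v` (m/s) columns; the last
#'   row's values are `NA`.
#' @export
add_steps <- function(track) {
  track <- dplyr::arrange(track, .data$time)
  n <- nrow(track)
  if (n < 2) {
    warn("track has fewer than 2 records; step series is empty")
    track$dt <- NA_real_
    track$d <- NA_real_
    track$v <- NA_real_
    return(track)
  }
  tsec <- as.numeric(track$time)
  if (any(diff(tsec) <= 0)) abort("timestamps must be strictly increasing")
  dt <- c(diff(tsec), NA_real_)
  d <- c(haversine_m(track$latitude[-n], track$longitude[-n],
                     track$latitude[-1], track$longitude[-1]), NA_real_)
  track$dt <- dt
  track$d <- d
  track$v <- d / dt
  track
}

#' Summarize one track
#'
#' @param track Record tibble; step columns are computed if absent.
#' @return One-row tibble: `n_records`, `D` (m), `T` (s), `v_eff` (m/s),
#'   `v_m` (m/s, mean instantaneous velocity).
#' @export
track_summary <- function(track) {
  if (!all(c("dt", "d", "v") %in% names(track))) track <- add_steps(track)
  D <- sum(track$d, na.rm = TRUE)
  T_ <- sum(track$dt, na.rm = TRUE)
  if (!is.finite(T_) || T_ <= 0) {
    abort("degenerate trajectory: total duration is zero")
  }
  tibble(
    n_records = nrow(track),
    D = D,
    T = T_,
    v_eff = D / T_,
    v_m = mean(track$v, na.rm = TRUE)
  )
}

#' Per-trip summaries for a cohort
#'
#' @param cohort Cohort tibble.
#' @return The cohort's metadata columns joined with [track_summary()] rows.
#' @export
cohort_summaries <- function(cohort) {
  sums <- purrr::map_dfr(cohort$track, track_summary)
  dplyr::bind_cols(
    cohort[, intersect(c("id", "source_filename", "school", "participant",
                         "mode", "companionship", "direction"), names(cohort))],
    sums
  )
}

.se <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Per-school distance, duration and velocity table
#'
#' For each school: mean and standard error of the trip distance `D` and
#' duration `T`, their min/max, and the mean, standard error, min and max of
#' the pooled instantaneous velocities. The `+/-` values are standard errors
#' of the mean. Groups with a single trip report `NA` standard errors; empty
#' groups are omitted.
#'
#' @param cohort Cohort tibble (step columns computed as needed).
#' @return A tibble with one row per school.
#' @export
school_table <- function(cohort) {
  sums <- cohort_summaries(cohort)
  vels <- purrr::map2_dfr(cohort$track, cohort$school, function(tr, sc) {
    if (!"v" %in% names(tr)) tr <- add_steps(tr)
    tibble(school = sc, v = tr$v[is.finite(tr$v)])
  })
  dist_dur <- sums %>%
    group_by(.data$school) %>%
    summarise(
      n_trips = dplyr::n(),
      D_mean = mean(.data$D), D_se = .se(.data$D),
      D_min = min(.data$D), D_max = max(.data$D),
      T_mean = mean(.data$T), T_se = .se(.data$T),
      T_min = min(.data$T), T_max = max(.data$T),
      .groups = "drop"
    )
  vel <- vels %>%
    group_by(.data$school) %>%
    summarise(
      v_mean = mean(.data$v), v_se = .se(.data$v),
      v_min = min(.data$v), v_max = max(.data$v),
      .groups = "drop"
    )
  left_join(dist_dur, vel, by = "school")
}

#' Cohort-level distribution table
#'
#' Mean, standard error, standard deviation, quartiles and range of a
#' numeric vector, in the layout used for trip duration / distance /
#' effective-speed validation tables.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `mean`, `se`, `sd`, `q1`, `q2`, `q3`, `min`, `max`,
#'   `n`.
#' @export
distribution_row <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("no finite values")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble(mean = mean(x), se = .se(x), sd = if (length(x) > 1) sd(x) else NA_real_,
         q1 = q[[1]], q2 = q[[2]], q3 = q[[3]],
         min = min(x), max = max(x), n = length(x))
}

#' Cohort quantile table for duration, distance and speeds
#'
#' @param cohort Cohort tibble.
#' @return A tibble with one [distribution_row()] per quantity (`T`, `D`,
#'   `v_eff`, `v`), identified by the `quantity` column.
#' @export
cohort_quantiles <- function(cohort) {
  sums <- cohort_summaries(cohort)
  v <- unlist(purrr::map(cohort$track, function(tr) {
    if (!"v" %in% names(tr)) tr <- add_steps(tr)
    tr$v[is.finite(tr$v)]
  }))
  bind_rows(
    mutate(distribution_row(sums$T), quantity = "T", .before = 1),
    mutate(distribution_row(sums$D), quantity = "D", .before = 1),
    mutate(distribution_row(sums$v_eff), quantity = "v_eff", .before = 1),
    mutate(distribution_row(v), quantity = "v", .before = 1)
  )
}
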