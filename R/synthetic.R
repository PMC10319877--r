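#' @title Synthetic pedestrian GPS cohorts with a ground-truth ledger
#' @name synthetic-data
#' @description
#' Generates labelled raw-dialect cohorts with the statistical structure the
#' pipeline assumes: walking-speed commutes to/from school sampled at 1 Hz
#' and thinned by a temporal gap model (17% of steps longer than 1 s, 99.8%
#' within 4 s), strongly autocorrelated GPS receiver error with a 3 m
#' marginal spread per axis, start-up outlier bursts at 20-90 m/s,
#' terminal dwell accumulation, and contaminant trips (declared vehicle
#' trips, undeclared vehicles, scatter blobs around the school, and tracks
#' with no school endpoint). Every record and every trip carries a truth
#' label so cleaning stages can be scored exactly.
NULL

#' Synthetic cohort parameters
#'
#' Defaults emulate the field conditions: per-participant mean walking speed
#' lognormal with mean 1.5 m/s and sd 0.25 m/s, trip durations uniform on
#' 300-700 s, gap probabilities `P(dt=2,3,4) = 0.12, 0.03, 0.018` and
#' `P(dt>4) = 0.002` (so `P(dt>1) = 0.17`, `P(dt<=4) = 0.998`), GPS noise
#' with 3 m marginal sd per axis and AR(1) autocorrelation 0.998 at 1 s
#' (receiver error drifts slowly rather than flickering), start-up bursts of
#' up to 6 fixes jumping at 20-90 m/s on 30% of trips, terminal dwell of
#' 60-180 s on 20% of trips, and contaminant fractions of 25% declared
#' vehicles, 10% undeclared vehicles, 8% scatter blobs and 8% no-OD tracks.
#'
#' @param n_per_school Participants per school.
#' @param schools School coordinate table (default [synthetic_schools()]).
#' @param n_schools Number of school codes used (first `n_schools` rows).
#' @param speed_mean,speed_sd Mean/sd (m/s) of the lognormal per-participant
#'   mean walking speed.
#' @param speed_cv_step Coefficient of variation of per-second speeds around
#'   the participant mean.
#' @param duration_range Trip duration range in seconds (uniform).
#' @param gap_probs Named probabilities for step intervals 2, 3, 4 s and
#'   `over4` (intervals 5-8 s, split evenly).
#' @param noise_sd Marginal GPS error sd per axis (m).
#' @param noise_phi Lag-1 autocorrelation of the GPS error at 1 s.
#' @param p_burst Probability a pedestrian trip starts with an outlier burst.
#' @param burst_max Maximum burst length (records).
#' @param burst_speed Range (m/s) of burst jump speeds.
#' @param burst_haccuracy Range (m) of burst accuracy radii.
#' @param p_dwell Probability of terminal dwell accumulation.
#' @param dwell_duration Dwell duration range (s).
#' @param dwell_jitter_sd Positional jitter sd (m) of dwell fixes.
#' @param haccuracy_range Accuracy radius range (m) of regular fixes.
#' @param segment_mean Mean street-segment duration (s) of the staircase
#'   walk.
#' @param heading_jitter_sd Per-segment heading jitter sd (degrees).
#' @param f_mode,f_vehicle,f_scatter,f_no_od Contamination fractions:
#'   declared non-pedestrian trips, undeclared vehicle trips, scatter blobs
#'   around the school, and coherent tracks with no school endpoint.
#' @param vehicle_speed_mean Mean speed (m/s) of vehicle contaminants.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_school = 26,
                        schools = synthetic_schools(),
                        n_schools = nrow(schools),
                        speed_mean = 1.5, speed_sd = 0.25,
                        speed_cv_step = 0.2,
                        duration_range = c(300, 700),
                        gap_probs = c(`2` = 0.12, `3` = 0.03, `4` = 0.018,
                                      over4 = 0.002),
                        noise_sd = 3, noise_phi = 0.998,
                        p_burst = 0.3, burst_max = 6,
                        burst_speed = c(20, 90),
                        burst_haccuracy = c(150, 500),
                        p_dwell = 0.2, dwell_duration = c(60, 180),
                        dwell_jitter_sd = 1.5,
                        haccuracy_range = c(5, 30),
                        segment_mean = 30, heading_jitter_sd = 5,
                        f_mode = 0.25, f_vehicle = 0.10,
                        f_scatter = 0.08, f_no_od = 0.08,
                        vehicle_speed_mean = 8) {
  stopifnot(sum(gap_probs) <= 1, all(gap_probs >= 0),
            f_mode + f_vehicle + f_scatter + f_no_od < 1,
            duration_range[1] > 0, duration_range[1] <= duration_range[2])
  spec <- as.list(environment())
  spec$schools <- schools[seq_len(min(n_schools, nrow(schools))), ]
  structure(spec, class = "cohort_spec")
}

# meters -> degrees at a reference latitude
.m_per_deg_lat <- function() pi * .earth_radius_m / 180
.m_per_deg_lon <- function(lat) .m_per_deg_lat() * cos(lat * pi / 180)

# AR(1) noise with marginal sd, stationary start
.ar1 <- function(n, sd, phi) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  e <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  e + phi^seq_len(n) * rnorm(1, 0, sd)
}

.draw_gaps <- function(n_max, gap_probs) {
  p1 <- 1 - sum(gap_probs)
  vals <- c(1, 2, 3, 4, 5:8)
  probs <- c(p1, gap_probs[["2"]], gap_probs[["3"]], gap_probs[["4"]],
             rep(gap_probs[["over4"]] / 4, 4))
  sample(vals, n_max, replace = TRUE, prob = probs)
}

# staircase walk outward from the school for `duration` seconds;
# returns 1 Hz truth positions in meters relative to the school
.walk_path <- function(duration, mean_speed, spec, straight = FALSE,
                       base = NULL) {
  n <- duration
  speeds <- mean_speed *
    rlnorm(n, -log(1 + spec$speed_cv_step^2) / 2,
           sqrt(log(1 + spec$speed_cv_step^2)))
  if (is.null(base)) base <- runif(1, 0, 360)
  seg_mean <- if (straight) 4 * spec$segment_mean else spec$segment_mean
  seg_len <- pmax(5, round(stats::rexp(n, 1 / seg_mean)))
  seg_id <- rep(seq_along(seg_len), seg_len)[seq_len(n)]
  headings <- base + 90 * (seg_id %% 2) +
    rnorm(max(seg_id), 0, spec$heading_jitter_sd)[seg_id]
  rad <- headings * pi / 180
  x <- c(0, cumsum(speeds * sin(rad)))
  y <- c(0, cumsum(speeds * cos(rad)))
  list(x = x, y = y, speeds = speeds, headings = c(headings, headings[n]))
}

.xy_to_latlon <- function(x, y, lat0, lon0) {
  list(latitude = lat0 + y / .m_per_deg_lat(),
       longitude = lon0 + x / .m_per_deg_lon(lat0))
}

.make_track <- function(class, school_row, nickname, trip_date, direction,
                        spec) {
  duration <- round(runif(1, spec$duration_range[1], spec$duration_range[2]))
  lat0 <- school_row$latitude
  lon0 <- school_row$longitude

  if (class == "scatter") {
    n <- sample(10:25, 1)
    gaps <- sample(1:3, n - 1, replace = TRUE)
    tsec <- cumsum(c(0, gaps))
    ll <- .xy_to_latlon(rnorm(n, 0, 40), rnorm(n, 0, 40), lat0, lon0)
    tr <- tibble(
      course = runif(n, 0, 360),
      haccuracy = round(runif(n, spec$haccuracy_range[1],
                              spec$haccuracy_range[2]), 1),
      latitude = ll$latitude, longitude = ll$longitude,
      speed = runif(n, 0, 1),
      time = .trip_start(trip_date) + tsec,
      nickname = nickname,
      truth = "clean"
    )
    return(list(track = tr, vi = NA_real_, duration = max(tsec),
                n_burst = 0L, n_dwell = 0L))
  }

  vi <- switch(class,
    pedestrian = , no_od = rlnorm(1, log(spec$speed_mean) -
        log(1 + (spec$speed_sd / spec$speed_mean)^2) / 2,
        sqrt(log(1 + (spec$speed_sd / spec$speed_mean)^2))),
    rlnorm(1, log(spec$vehicle_speed_mean) - 0.5 * 0.1^2, 0.1))
  straight <- class %in% c("mode_contaminant", "unlabeled_vehicle")
  base <- NULL
  off_dir <- NULL
  if (class == "no_od") {
    # start well away from the school and keep heading outward, so neither
    # endpoint can come near it
    off_dir <- runif(1, 0, 2 * pi)
    base <- off_dir * 180 / pi - 45 + rnorm(1, 0, 10)
  }
  path <- .walk_path(duration, vi, spec, straight = straight, base = base)
  x <- path$x; y <- path$y
  if (class == "no_od") {
    off <- runif(1, 600, 1200)
    x <- x + off * sin(off_dir)
    y <- y + off * cos(off_dir)
  }
  if (direction == "home_to_school" && class != "no_od") {
    x <- rev(x); y <- rev(y)
    path$speeds <- rev(path$speeds)
    path$headings <- rev(path$headings)
  }

  n_pts <- length(x)
  # thin the 1 Hz truth by the temporal gap model
  gaps <- .draw_gaps(n_pts, spec$gap_probs)
  keep_t <- cumsum(c(0, gaps))
  keep_t <- keep_t[keep_t <= n_pts - 1]
  idx <- keep_t + 1

  noise_x <- .ar1(n_pts, spec$noise_sd, spec$noise_phi)
  noise_y <- .ar1(n_pts, spec$noise_sd, spec$noise_phi)
  ll <- .xy_to_latlon(x[idx] + noise_x[idx], y[idx] + noise_y[idx],
                      lat0, lon0)
  nk <- length(idx)
  t_start <- .trip_start(trip_date)
  tr <- tibble(
    course = (path$headings[idx] %% 360),
    haccuracy = round(runif(nk, spec$haccuracy_range[1],
                            spec$haccuracy_range[2]), 1),
    latitude = ll$latitude, longitude = ll$longitude,
    speed = pmax(0, path$speeds[pmin(idx, n_pts - 1)] + rnorm(nk, 0, 0.1)),
    time = t_start + keep_t,
    nickname = nickname,
    truth = "clean"
  )

  n_burst <- 0L
  if (class == "pedestrian" && runif(1) < spec$p_burst) {
    n_burst <- sample.int(spec$burst_max, 1)
    jump <- runif(n_burst, spec$burst_speed[1], spec$burst_speed[2])
    ang <- runif(n_burst, 0, 2 * pi)
    # walk backwards in time from the first true fix
    bx <- x[idx[1]] + cumsum(jump * sin(ang))
    by <- y[idx[1]] + cumsum(jump * cos(ang))
    bll <- .xy_to_latlon(rev(bx), rev(by), lat0, lon0)
    burst <- tibble(
      course = runif(n_burst, 0, 360),
      haccuracy = round(runif(n_burst, spec$burst_haccuracy[1],
                              spec$burst_haccuracy[2]), 1),
      latitude = bll$latitude, longitude = bll$longitude,
      speed = rev(jump),
      time = t_start - seq(n_burst, 1),
      nickname = nickname,
      truth = "outlier"
    )
    tr <- bind_rows(burst, tr)
  }

  n_dwell <- 0L
  if (class == "pedestrian" && runif(1) < spec$p_dwell) {
    n_dwell <- round(runif(1, spec$dwell_duration[1], spec$dwell_duration[2]))
    fx <- x[idx[length(idx)]] + noise_x[idx[length(idx)]]
    fy <- y[idx[length(idx)]] + noise_y[idx[length(idx)]]
    dll <- .xy_to_latlon(fx + rnorm(n_dwell, 0, spec$dwell_jitter_sd),
                         fy + rnorm(n_dwell, 0, spec$dwell_jitter_sd),
                         lat0, lon0)
    dwell <- tibble(
      course = runif(n_dwell, 0, 360),
      haccuracy = round(runif(n_dwell, spec$haccuracy_range[1],
                              spec$haccuracy_range[2]), 1),
      latitude = dll$latitude, longitude = dll$longitude,
      speed = 0,
      time = tr$time[[nrow(tr)]] + seq_len(n_dwell),
      nickname = nickname,
      truth = "dwell"
    )
    tr <- bind_rows(tr, dwell)
  }

  list(track = tr, vi = vi, duration = duration,
       n_burst = n_burst, n_dwell = n_dwell)
}

.trip_start <- function(trip_date) {
  as.POSIXct(paste(trip_date, "08:00:00"), tz = "UTC") +
    sample.int(1800, 1)
}

.walk_tokens <- c("WALK", "peu", "walk", "CAMINANT")
.vehicle_tokens <- c("tren", "BUS", "bici", "METRO", "car", "patinet")
.comp_tokens <- c("ALONE", "sol", "ACCOMPANIED", "amics")

#' Generate a labelled synthetic cohort
#'
#' Trip classes are allocated deterministically from the spec's contamination
#' fractions (rounded per cohort), then shuffled across schools. Classes:
#' `pedestrian`, `mode_contaminant` (declared vehicle), `unlabeled_vehicle`
#' (vehicle speeds, no mode token), `scatter` (a blob of fixes around the
#' school) and `no_od` (a coherent walk with no school endpoint).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(spec, seed)`.
#' @return A `synthetic_cohort` list: `cohort` (cohort tibble whose tracks
#'   carry a per-record `truth` label: `clean` / `outlier` / `dwell`),
#'   `ledger` (per-trip truth: `id`, `class`, `school`, `direction`,
#'   `target_speed`, `duration_s`, `n_burst`, `n_dwell`, `n_records`),
#'   `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  set.seed(seed)
  schools <- spec$schools
  n_total <- nrow(schools) * spec$n_per_school
  n_mode <- round(spec$f_mode * n_total)
  n_veh <- round(spec$f_vehicle * n_total)
  n_scat <- round(spec$f_scatter * n_total)
  n_nood <- round(spec$f_no_od * n_total)
  classes <- sample(c(rep("mode_contaminant", n_mode),
                      rep("unlabeled_vehicle", n_veh),
                      rep("scatter", n_scat),
                      rep("no_od", n_nood),
                      rep("pedestrian", n_total - n_mode - n_veh -
                            n_scat - n_nood)))
  dates <- seq(as.Date("2018-11-05"), as.Date("2018-11-16"), by = "day")
  school_dates <- setNames(sample(dates, nrow(schools), replace = TRUE),
                           schools$school)

  rows <- vector("list", n_total)
  ledger <- vector("list", n_total)
  i <- 0
  for (s in seq_len(nrow(schools))) {
    for (p in seq_len(spec$n_per_school)) {
      i <- i + 1
      cls <- classes[[i]]
      code <- schools$school[[s]]
      trip_date <- school_dates[[code]]
      direction <- sample(c("home_to_school", "school_to_home"), 1)
      mode_tok <- switch(cls,
        mode_contaminant = sample(.vehicle_tokens, 1),
        unlabeled_vehicle = NA_character_,
        sample(c(.walk_tokens, NA_character_), 1,
               prob = c(rep(0.225, 4), 0.1)))
      comp_tok <- sample(c(.comp_tokens, NA_character_), 1,
                         prob = c(rep(0.125, 4), 0.5))
      nick <- paste(stats::na.omit(c(tolower(code), sprintf("%04d", p),
                                     mode_tok, comp_tok)), collapse = "_")
      made <- .make_track(cls, schools[s, ], nick, trip_date, direction, spec)
      tr <- made$track
      rows[[i]] <- tibble(
        id = i,
        source_filename = paste0(format(trip_date), "_", nick, ".csv"),
        trip_date = trip_date,
        nickname = nick,
        school = code,
        participant = sprintf("%04d", p),
        mode = parse_nickname(nick)$mode,
        companionship = parse_nickname(nick)$companionship,
        school_matched = TRUE,
        direction = direction,
        n_records = nrow(tr),
        track = list(tr)
      )
      ledger[[i]] <- tibble(
        id = i, class = cls, school = code, direction = direction,
        target_speed = made$vi, duration_s = made$duration,
        n_burst = made$n_burst, n_dwell = made$n_dwell,
        n_records = nrow(tr)
      )
    }
  }
  structure(list(cohort = bind_rows(rows), ledger = bind_rows(ledger),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic GPS cohort: %d trips, %d records\n",
              nrow(x$cohort), sum(x$cohort$n_records)))
  print(table(x$ledger$class))
  invisible(x)
}

#' Score a cleaning run against the generator's truth ledger
#'
#' Confusion counts per cleaning stage: stage 1 against the vehicle trip
#' labels, stage 2 against the scatter / no-OD labels, stage 3 at record
#' level against the injected outlier and dwell labels of pedestrian trips
#' that reached it.
#'
#' @param result A `cleaning_result` from [clean_cohort()] run on the
#'   synthetic cohort.
#' @param synth The `synthetic_cohort` the pipeline ran on.
#' @return A tibble with one row per metric: `stage`, `metric`, `value`,
#'   `numerator`, `denominator`.
#' @export
truth_eval <- function(result, synth) {
  ledger <- synth$ledger
  disp <- result$dispositions
  if (!all(disp$id %in% ledger$id)) abort("dispositions and ledger do not match")

  removed_at <- function(stage) disp$id[disp$stage == stage &
                                          disp$outcome == "removed"]
  ids_of <- function(cls) ledger$id[ledger$class %in% cls]

  s1 <- removed_at("non_pedestrian")
  veh <- ids_of(c("mode_contaminant", "unlabeled_vehicle"))
  mode_ids <- ids_of("mode_contaminant")
  s2 <- removed_at("od_validation")
  invalid <- ids_of(c("scatter", "no_od"))
  # invalid trips can only reach stage 2 if stage 1 kept them
  invalid_reaching <- setdiff(invalid, s1)

  # stage 3: pedestrian trips that reached it
  ped <- ids_of("pedestrian")
  reached3 <- setdiff(setdiff(ped, s1), s2)
  discarded3 <- intersect(removed_at("outliers"), reached3)
  truth_of <- function(ids) {
    tr <- synth$cohort$track[match(ids, synth$cohort$id)]
    unlist(purrr::map(tr, "truth"))
  }
  rem_rec <- result$removed_records
  rem_rec <- rem_rec[rem_rec$id %in% reached3, , drop = FALSE]
  removed_truth <- c(as.character(rem_rec$truth), truth_of(discarded3))
  all_truth <- truth_of(reached3)

  n_out <- sum(all_truth == "outlier")
  n_clean <- sum(all_truth == "clean")
  metric <- function(stage, name, num, den) {
    tibble(stage = stage, metric = name,
           value = if (den > 0) num / den else NA_real_,
           numerator = num, denominator = den)
  }
  bind_rows(
    metric("non_pedestrian", "mode_recall",
           length(intersect(s1, mode_ids)), length(mode_ids)),
    metric("non_pedestrian", "vehicle_recall",
           length(intersect(s1, veh)), length(veh)),
    metric("non_pedestrian", "false_positive_rate",
           length(setdiff(s1, veh)), nrow(ledger) - length(veh)),
    metric("od_validation", "invalid_recall",
           length(intersect(s2, invalid_reaching)),
           length(invalid_reaching)),
    metric("od_validation", "pedestrian_rejected",
           length(intersect(s2, ped)), length(setdiff(ped, s1))),
    metric("outliers", "outlier_record_recall",
           sum(removed_truth == "outlier"), n_out),
    metric("outliers", "clean_false_removal",
           sum(removed_truth == "clean"), n_clean),
    metric("outliers", "trajectories_discarded",
           length(discarded3), length(reached3))
  )
}
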