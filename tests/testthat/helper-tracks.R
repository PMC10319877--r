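# Builders for deterministic fixture tracks; all geometry is exercised at
# the equator unless a latitude is supplied, so meters-per-degree is exact.

.m_per_deg <- pi * 6371008.8 / 180

base_time <- function() as.POSIXct("2018-11-05 08:00:00", tz = "UTC")

# straight eastbound walk at constant speed, 1 Hz
straight_track <- function(n = 401, v = 1.5, lat0 = 0, lon0 = 0,
                           nickname = "zaf_0001_peu", haccuracy = 10) {
  tibble::tibble(
    course = 90,
    haccuracy = haccuracy,
    latitude = lat0,
    longitude = lon0 + (0:(n - 1)) * v / (.m_per_deg * cos(lat0 * pi / 180)),
    speed = v,
    time = base_time() + 0:(n - 1),
    nickname = nickname
  )
}

# stationary track (same position repeated)
stationary_track <- function(n = 50, lat0 = 0, lon0 = 0,
                             nickname = "zaf_0002_peu") {
  tibble::tibble(
    course = 0, haccuracy = 10, latitude = lat0, longitude = lon0,
    speed = 0, time = base_time() + 0:(n - 1), nickname = nickname
  )
}

# track from per-second speeds along a fixed heading (deg)
speeds_track <- function(speeds, heading = 90, lat0 = 0, lon0 = 0,
                         nickname = "zaf_0003_peu") {
  rad <- heading * pi / 180
  x <- c(0, cumsum(speeds * sin(rad)))
  y <- c(0, cumsum(speeds * cos(rad)))
  n <- length(x)
  tibble::tibble(
    course = heading, haccuracy = 10,
    latitude = lat0 + y / .m_per_deg,
    longitude = lon0 + x / (.m_per_deg * cos(lat0 * pi / 180)),
    speed = c(speeds, speeds[length(speeds)]),
    time = base_time() + 0:(n - 1),
    nickname = nickname
  )
}

# spec for a noiseless, contamination-free cohort of constant-speed walkers
clean_cohort_spec <- function(...) {
  cohort_spec(speed_sd = 1e-9, speed_cv_step = 1e-9, noise_sd = 0,
              p_burst = 0, p_dwell = 0,
              f_mode = 0, f_vehicle = 0, f_scatter = 0, f_no_od = 0, ...)
}

# cache expensive shared cohorts across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_synth <- function() {
  cached("default_synth",
         simulate_cohort(cohort_spec(n_per_school = 8), seed = 101))
}

# gaps and GPS noise on, but no bursts, dwell or contaminant trips
clean_synth <- function() {
  cached("clean_synth", simulate_cohort(
    cohort_spec(n_per_school = 4, p_burst = 0, p_dwell = 0,
                f_mode = 0, f_vehicle = 0, f_scatter = 0, f_no_od = 0),
    seed = 202))
}
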