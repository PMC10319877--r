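school0 <- tibble::tibble(school = "ZAF", latitude = 0, longitude = 0)

test_that("declared vehicles and abnormal unknown-mode speeds are removed", {
  walk <- straight_track(400, v = 1.4)
  train <- straight_track(400, v = 6.0, nickname = "sgv_0601_tren")
  fast_unknown <- straight_track(400, v = 6.0, nickname = "zaf_0099")
  slow_unknown <- straight_track(400, v = 1.2, nickname = "zaf_0098")
  co <- as_cohort(list(walk, train, fast_unknown, slow_unknown))
  out <- filter_non_pedestrian(co)
  expect_equal(out$removed$nickname, c("sgv_0601_tren", "zaf_0099"))
  expect_match(out$dispositions$reason[[2]], "mode=train")
  expect_match(out$dispositions$reason[[3]], "v_eff")
  expect_equal(out$kept$nickname, c("zaf_0001_peu", "zaf_0098"))
})

test_that("origin-destination validation accepts anchored tracks only", {
  pol <- cleaning_policy()
  # 400-record walk ending 30 m from the school, starting ~630 m away
  tr <- straight_track(401, v = 1.5, lon0 = -630 / .m_per_deg)
  expect_true(validate_od(tr, c(0, 0), pol)$valid)

  # a handful of fixes scattered around the school
  set.seed(2)
  blob <- stationary_track(12)
  blob$latitude <- rnorm(12, 0, 40 / .m_per_deg)
  blob$longitude <- rnorm(12, 0, 40 / .m_per_deg)
  res <- validate_od(blob, c(0, 0), pol)
  expect_false(res$valid)

  # coherent walk that never touches the school
  far <- straight_track(401, v = 1.5, lon0 = 2000 / .m_per_deg)
  res2 <- validate_od(far, c(0, 0), pol)
  expect_false(res2$valid)
  expect_match(res2$reason, "no endpoint")

  expect_error(validate_od(tr, c(NA, NA), pol), "coordinates")
})

test_that("start-up bursts are removed and the clean walk is preserved", {
  walk <- straight_track(400, v = 1.4)
  burst <- walk[1:5, ]
  burst$time <- walk$time[[1]] - (5:1)
  burst$latitude <- burst$latitude + (5:1) * 90 / .m_per_deg  # 90 m/s jumps
  tr <- dplyr::bind_rows(burst, walk)
  out <- remove_outliers(tr)
  expect_false(out$discarded)
  expect_equal(nrow(out$removed), 5)
  expect_equal(out$track$time, walk$time)
  expect_true(max(out$track$v, na.rm = TRUE) <= cleaning_policy()$v_outlier_max)

  # clean track is untouched
  clean <- remove_outliers(walk)
  expect_equal(nrow(clean$removed), 0)
  expect_equal(clean$track$latitude, walk$latitude)
})

test_that("records stay in order and bookkeeping balances after cleanup", {
  set.seed(5)
  walk <- straight_track(300, v = 1.4)
  spiked <- walk
  hit <- sort(sample(20:280, 15))
  spiked$latitude[hit] <- spiked$latitude[hit] + 200 / .m_per_deg
  out <- remove_outliers(spiked)
  expect_false(out$discarded)
  expect_true(all(diff(as.numeric(out$track$time)) > 0))
  expect_equal(nrow(out$track) + nrow(out$removed), nrow(spiked))
  expect_true(max(out$track$v, na.rm = TRUE) <= 10)
})

test_that("a trajectory drowning in noise is discarded whole", {
  set.seed(6)
  walk <- straight_track(200, v = 1.4)
  noisy <- walk
  hit <- sample(200, 80)  # 40% displaced records
  noisy$latitude[hit] <- noisy$latitude[hit] + runif(80, 100, 400) / .m_per_deg
  out <- remove_outliers(noisy)
  expect_true(out$discarded)
  expect_null(out$track)
})

test_that("a stationary terminal segment collapses to one record", {
  walk <- straight_track(301, v = 1.5)
  dwell <- walk[301, ]
  dwell <- dwell[rep(1, 120), ]
  dwell$time <- walk$time[[301]] + 1:120
  set.seed(7)
  dwell$latitude <- dwell$latitude + rnorm(120, 0, 2 / .m_per_deg)
  tr <- dplyr::bind_rows(walk, dwell)
  out <- remove_outliers(tr)
  expect_false(out$discarded)
  expect_true(all(out$removed$removal == "dwell"))
  # everything after the first record of the dwell segment goes
  expect_lt(nrow(out$track), 301 + 5)
  expect_equal(out$track$time[[1]], walk$time[[1]])
})

test_that("cohort-level cleaning keeps exact record bookkeeping", {
  synth <- default_synth()
  res <- clean_cohort(synth$cohort, synthetic_schools())
  g <- glance(res)
  expect_equal(g$records_in, g$records_kept + g$records_removed)
  expect_equal(nrow(res$cohort) + sum(res$report$trajectories_removed),
               nrow(synth$cohort))
  disp <- tidy(res)
  expect_setequal(disp$id, synth$cohort$id)  # dispositions exhaustive
  # all kept tracks respect the velocity cap
  caps <- purrr::map_lgl(res$cohort$track, function(tr) {
    max(tr$v, na.rm = TRUE) <= res$policy$v_outlier_max
  })
  expect_true(all(caps))
  expect_error(clean_cohort(synth$cohort, school0), "school coordinates")
})
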