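test_that("haversine distance matches the arc-length oracle", {
  expect_equal(haversine_m(10, 20, 10, 20), 0)
  # meridian arc: R * dphi
  oracle <- 6371008.8 * 0.001 * pi / 180
  expect_equal(haversine_m(0, 0, 0.001, 0), oracle, tolerance = 1e-3 / oracle)
  # symmetric
  expect_equal(haversine_m(41.4, 2.1, 41.5, 2.2),
               haversine_m(41.5, 2.2, 41.4, 2.1))
  # consecutive processed-file fixes: printed step distance 2.367819 m,
  # inputs rounded at 6 dp allow ~0.15 m
  expect_equal(haversine_m(41.413296, 2.187355, 41.413310, 2.187333),
               2.367819, tolerance = 0.15 / 2.367819)
})

test_that("step series follows the time-advanced convention", {
  tr <- stationary_track(2)
  st <- add_steps(tr)
  expect_equal(st$dt, c(1, NA))
  expect_equal(st$d, c(0, NA))
  expect_equal(st$v, c(0, NA))

  # a 2 s interval with the printed displacement halves into velocity
  tr2 <- tibble::tibble(
    course = 0, haccuracy = 25,
    latitude = c(41.410504, 41.410474), longitude = c(2.183065, 2.183081),
    speed = 0.2,
    time = as.POSIXct(c("2018-11-09 10:00:20", "2018-11-09 10:00:22"),
                      tz = "UTC"),
    nickname = "zaf_0067_peu")
  st2 <- add_steps(tr2)
  expect_equal(st2$dt[[1]], 2)
  expect_equal(st2$d[[1]], 3.655477, tolerance = 0.3 / 3.655477)
  expect_equal(st2$v[[1]], st2$d[[1]] / 2)

  # algebraic identity v * dt == d on a random synthetic track
  synth_tr <- default_synth()$cohort$track[[1]]
  st3 <- add_steps(synth_tr)
  ok <- !is.na(st3$v)
  expect_equal(st3$v[ok] * st3$dt[ok], st3$d[ok], tolerance = 1e-12)

  expect_warning(add_steps(stationary_track(1)), "fewer than 2")
})

test_that("trip summaries obey closed forms and conservation", {
  tr <- straight_track(401, v = 1.5)  # 400 steps of 1 s
  s <- track_summary(tr)
  expect_equal(s$D, 600, tolerance = 1e-6)
  expect_equal(s$T, 400)
  expect_equal(s$v_eff, 1.5, tolerance = 1e-6)

  # single step dt=2, dist=3
  tr2 <- straight_track(2, v = 3)
  tr2$time[2] <- tr2$time[1] + 2
  s2 <- track_summary(tr2)
  expect_equal(s2$D, 3, tolerance = 1e-6)
  expect_equal(s2$T, 2)
  expect_equal(s2$v_eff, 1.5, tolerance = 1e-6)

  expect_error(suppressWarnings(track_summary(stationary_track(1))),
               "duration")
})

test_that("summaries match an independent timestamp oracle on a cohort", {
  co <- clean_synth()$cohort
  sums <- cohort_summaries(co)
  t_span <- purrr::map_dbl(co$track, function(tr) {
    as.numeric(max(tr$time)) - as.numeric(min(tr$time))
  })
  expect_equal(sums$T, t_span)
  expect_equal(mean(sums$T), mean(t_span))
  # conservation and bounds per trip
  for (i in seq_len(4)) {
    st <- add_steps(co$track[[i]])
    expect_equal(sum(st$d, na.rm = TRUE), sums$D[[i]], tolerance = 1e-9)
    expect_gte(sums$D[[i]],
               haversine_m(st$latitude[[1]], st$longitude[[1]],
                           st$latitude[[nrow(st)]], st$longitude[[nrow(st)]]))
    v <- st$v[!is.na(st$v)]
    expect_gte(sums$v_eff[[i]], min(v))
    expect_lte(sums$v_eff[[i]], max(v))
  }
})

test_that("per-school tables report means, standard errors and extremes", {
  tr <- straight_track(101, v = 1.5)
  co <- as_cohort(list(tr, tr, straight_track(201, v = 1.0,
                                              nickname = "ver_0001_peu")))
  co$school <- c("ZAF", "ZAF", "VER")
  tab <- school_table(co)
  zaf <- tab[tab$school == "ZAF", ]
  expect_equal(zaf$n_trips, 2)
  expect_equal(zaf$D_se, 0)  # identical duplicated trips
  expect_equal(zaf$D_min, zaf$D_max)
  ver <- tab[tab$school == "VER", ]
  expect_true(is.na(ver$D_se))  # single-trip group has no spread
  expect_equal(ver$T_mean, 200)

  # pooled velocity recovery: simulated speeds around 1.5
  set.seed(9)
  tracks <- purrr::map(1:20, function(i) {
    speeds_track(pmax(0, rnorm(120, 1.5, 0.2)),
                 nickname = sprintf("zaf_%04d_peu", i))
  })
  co2 <- as_cohort(tracks)
  co2$school <- "ZAF"
  tab2 <- school_table(co2)
  expect_lt(abs(tab2$v_mean - 1.5), 3 * tab2$v_se + 1e-3)
})

test_that("cohort quantile table covers T, D, v_eff and pooled v", {
  q <- cohort_quantiles(clean_synth()$cohort)
  expect_setequal(q$quantity, c("T", "D", "v_eff", "v"))
  expect_true(all(q$q1 <= q$q2 & q$q2 <= q$q3))
})
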