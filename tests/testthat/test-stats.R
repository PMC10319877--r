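test_that("log-velocity normalization behaves at its fixed points", {
  v <- rep(1.3, 50)
  lv <- log_velocity(v)
  expect_equal(lv$u, rep(0, 50))
  lv2 <- log_velocity(c(rep(1, 9), exp(1)), v_m = 1)
  expect_equal(lv2$u[[10]], 1)
  expect_error(log_velocity(rep(0, 10)), "zero")
  lv3 <- log_velocity(c(0, 1, 2, NA))
  expect_equal(lv3$n_zero, 1)
  expect_true(is.na(lv3$u[[1]]) && is.na(lv3$u[[4]]))
})

test_that("log-velocity of lognormal speeds matches the closed form", {
  # if v ~ LN(mu, sigma) then E[u] = mu - ln E[v] = -sigma^2 / 2
  set.seed(11)
  sigma <- 0.4
  v <- rlnorm(20000, log(1.5), sigma)
  u <- log_velocity(v)$u
  se <- sd(u) / sqrt(length(u))
  expect_lt(abs(mean(u) - (-sigma^2 / 2)), 3 * se + 3e-3)
})

test_that("MSD matches ballistic and stationary closed forms", {
  co <- as_cohort(list(straight_track(401, v = 1.5),
                       straight_track(401, v = 1.5,
                                      nickname = "ver_0001_peu")))
  msd <- cohort_msd(co, max_lag = 100, n_boot = 50, seed = 1)
  expect_equal(msd$msd[msd$lag == 0], 0)
  expect_equal(msd$msd[-1], (1.5 * msd$lag[-1])^2, tolerance = 1e-3)
  expect_true(all(msd$ci_low <= msd$msd & msd$msd <= msd$ci_high))

  still <- as_cohort(list(stationary_track(200), stationary_track(200)))
  msd0 <- cohort_msd(still, max_lag = 50, n_boot = 20, seed = 1)
  expect_true(all(msd0$msd == 0))
})

test_that("MSD of a lattice random walk grows diffusively at small lags", {
  set.seed(12)
  tracks <- purrr::map(1:30, function(i) {
    steps <- sample(c(-1, 1), 400, replace = TRUE)
    axis <- sample(c(TRUE, FALSE), 400, replace = TRUE)
    x <- c(0, cumsum(ifelse(axis, steps, 0)))
    y <- c(0, cumsum(ifelse(!axis, steps, 0)))
    tibble::tibble(course = 0, haccuracy = 10,
                   latitude = y / .m_per_deg, longitude = x / .m_per_deg,
                   speed = 1, time = base_time() + 0:400,
                   nickname = sprintf("zaf_%04d_peu", i))
  })
  msd <- cohort_msd(as_cohort(tracks), max_lag = 20, n_boot = 200, seed = 2)
  # MSD(tau) = tau * (1 m)^2 for this walk; check within the bootstrap band
  sel <- msd$lag %in% 1:20
  expect_true(all(msd$ci_low[sel] - 1e-6 <= msd$lag[sel] &
                    msd$lag[sel] <= msd$ci_high[sel] + 1e-6))
})

test_that("autocorrelation is 1 at lag zero and white noise decorrelates", {
  set.seed(13)
  white <- purrr::map(1:40, function(i) {
    speeds_track(1.5 * exp(rnorm(1000, 0, 0.3)),
                 nickname = sprintf("zaf_%04d_peu", i))
  })
  co <- as_cohort(white)
  ac <- cohort_vacf(co, max_lag = 5, n_boot = 300, seed = 3)
  expect_identical(ac$c[ac$lag == 0], 1)
  for (l in 1:5) {
    row <- ac[ac$lag == l, ]
    expect_true(row$ci_low <= 0 && 0 <= row$ci_high)
    expect_lt(abs(row$c), 0.05)
  }
})

test_that("an AR(1) log-velocity process recovers its lag-1 coefficient", {
  set.seed(14)
  rho <- 0.6
  tracks <- purrr::map(1:40, function(i) {
    u <- as.numeric(stats::arima.sim(list(ar = rho), 400, sd = 0.3))
    speeds_track(1.5 * exp(u), nickname = sprintf("zaf_%04d_peu", i))
  })
  ac <- cohort_vacf(as_cohort(tracks), max_lag = 3, n_boot = 100, seed = 4)
  c1 <- ac$c[ac$lag == 1]
  # 3 standard errors across trips
  per_trip <- purrr::map_dbl(tracks, function(tr) {
    u <- log(add_steps(tr)$v[1:399] / mean(add_steps(tr)$v[1:399]))
    stats::acf(u, plot = FALSE, lag.max = 1)$acf[2]
  })
  se <- sd(per_trip) / sqrt(length(per_trip))
  expect_lt(abs(c1 - rho), 3 * se + 0.01)
})

test_that("velocity histograms integrate to one on their support", {
  co <- clean_synth()$cohort
  pv <- velocity_pdf(co, "v")
  expect_equal(sum(pv$density) * 0.1, 1, tolerance = 1e-6)
  pu <- velocity_pdf(co, "u")
  expect_equal(sum(pu$density) * 0.1, 1, tolerance = 1e-6)
  expect_equal(attr(pu, "scale"), "u")
})
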