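test_that("generation is fully deterministic given spec and seed", {
  spec <- cohort_spec(n_per_school = 2, n_schools = 3)
  a <- simulate_cohort(spec, seed = 42)
  b <- simulate_cohort(spec, seed = 42)
  expect_identical(a$cohort$track, b$cohort$track)
  expect_identical(a$ledger, b$ledger)
  c_ <- simulate_cohort(spec, seed = 43)
  expect_false(identical(a$cohort$track, c_$cohort$track))
})

test_that("the temporal gap model realizes the target probabilities", {
  synth <- default_synth()
  dt <- unlist(purrr::map(synth$cohort$track[synth$ledger$class ==
                                               "pedestrian"], function(tr) {
    diff(as.numeric(tr$time))
  }))
  dt <- dt[dt >= 1]  # pedestrians only, burst/dwell inserts are 1 s anyway
  expect_gt(length(dt), 10000)
  p_gap <- mean(dt > 1)
  se <- sqrt(0.17 * 0.83 / length(dt))
  expect_lt(abs(p_gap - 0.17), 3 * se + 0.01)
  expect_gte(mean(dt <= 4), 0.995)
})

test_that("a noiseless uncontaminated cohort passes every stage untouched", {
  synth <- simulate_cohort(clean_cohort_spec(n_per_school = 3, n_schools = 4),
                           seed = 5)
  res <- clean_cohort(synth$cohort, synthetic_schools())
  expect_equal(nrow(res$cohort), nrow(synth$cohort))
  expect_equal(sum(res$report$records_removed), 0)
  for (i in seq_len(nrow(res$cohort))) {
    expect_equal(nrow(res$cohort$track[[i]]),
                 nrow(synth$cohort$track[[i]]))
  }
})

test_that("declared-mode contaminants are removed exactly by their labels", {
  spec <- cohort_spec(n_per_school = 10, n_schools = 3, f_mode = 0.3,
                      f_vehicle = 0, f_scatter = 0, f_no_od = 0)
  synth <- simulate_cohort(spec, seed = 6)
  expect_equal(sum(synth$ledger$class == "mode_contaminant"), 9)  # 30% of 30
  out <- filter_non_pedestrian(synth$cohort)
  expect_setequal(out$removed$id,
                  synth$ledger$id[synth$ledger$class == "mode_contaminant"])
})

test_that("truth scoring recovers the injected contamination", {
  synth <- default_synth()
  res <- clean_cohort(synth$cohort, synthetic_schools())
  ev <- truth_eval(res, synth)
  val <- function(m) ev$value[ev$metric == m]
  expect_equal(val("mode_recall"), 1)
  expect_equal(val("vehicle_recall"), 1)
  expect_equal(val("invalid_recall"), 1)
  expect_gte(val("outlier_record_recall"), 0.99)
  expect_lt(val("clean_false_removal"), 0.02)
})

test_that("clean cohorts recover the target walking speed", {
  synth <- clean_synth()
  sums <- cohort_summaries(synth$cohort)
  se <- sd(sums$v_eff) / sqrt(nrow(sums))
  expect_lt(abs(mean(sums$v_eff) - 1.5), 3 * se + 0.03)
  # trajectory durations match the drawn ones
  expect_equal(sums$T, synth$ledger$duration_s, tolerance = 0.02)
})

test_that("generated files carry protocol-compliant names and schemas", {
  synth <- simulate_cohort(cohort_spec(n_per_school = 1, n_schools = 5),
                           seed = 9)
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}_[a-z]{3}_\\d{4}",
                        synth$cohort$source_filename)))
  expect_true(all(purrr::map_lgl(synth$cohort$track, function(tr) {
    all(c("course", "haccuracy", "latitude", "longitude", "speed",
          "time", "nickname") %in% names(tr))
  })))
  # one nickname per trajectory
  expect_true(all(purrr::map_lgl(synth$cohort$track, function(tr) {
    length(unique(tr$nickname)) == 1
  })))
})
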