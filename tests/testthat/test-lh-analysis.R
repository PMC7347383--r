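mk_series <- function(y, dt = 3) {
  data.frame(time_min = seq(0, by = dt, length.out = length(y)),
             lh_ng_per_ml = y, animal_id = "t")
}

test_that("the sweep calls nadir-to-peak increments strictly over 25%", {
  calls <- detect_pulses(mk_series(c(1.0, 0.9, 1.2, 1.0, 1.35, 1.3)))
  expect_equal(nrow(calls), 2)
  expect_equal(calls$nadir_value, c(0.9, 1.0))
  expect_equal(calls$peak_value, c(1.2, 1.35))
  expect_equal(calls$increment_pct, c(100 * 0.3 / 0.9, 35), tolerance = 1e-9)
  expect_equal(calls$amplitude, c(0.3, 0.35), tolerance = 1e-9)
  # an increment of exactly 25% is NOT a pulse
  expect_equal(nrow(detect_pulses(mk_series(c(2.2, 2.0, 2.5, 2.3)))), 0)
  # a monotone decreasing series has no pulses
  expect_equal(nrow(detect_pulses(mk_series(c(5, 4, 3, 2, 1)))), 0)
})

test_that("degenerate pulse-caller inputs error as specified", {
  expect_error(detect_pulses(mk_series(c(1, 2))), "at least 3")
  expect_error(detect_pulses(mk_series(c(1, 0, 2)),
                             pulse_criteria(min_value = 0)), "zero nadir")
  # with the default floor, a zero nadir is simply not a valid pulse anchor
  expect_equal(nrow(detect_pulses(mk_series(c(1, 0, 2, 1.9)))), 0)
})

test_that("sweep calls equal the brute-force oracle on random series", {
  set.seed(123)
  for (rep in 1:300) {
    n <- sample(4:20, 1)
    y <- round(exp(rnorm(n, log(2), 0.4)), 2)
    calls <- detect_pulses(mk_series(y))
    got <- match(calls$peak_time, mk_series(y)$time_min)
    expect_identical(as.integer(got), as.integer(oracle_pulse_peaks(y)))
  }
})

test_that("pulse calls are scale invariant and their amplitudes scale", {
  set.seed(9)
  for (rep in 1:20) {
    y <- exp(rnorm(30, log(2), 0.5))
    base <- detect_pulses(mk_series(y))
    for (c_mult in c(0.1, 3, 42)) {
      scaled <- detect_pulses(mk_series(c_mult * y))
      expect_equal(scaled$peak_time, base$peak_time)
      expect_equal(scaled$amplitude, c_mult * base$amplitude,
                   tolerance = 1e-9)
    }
  }
})

test_that("an additive positive shift never increases the pulse count", {
  set.seed(21)
  for (rep in 1:30) {
    y <- exp(rnorm(25, log(1.5), 0.5))
    counts <- vapply(seq(0, 4, by = 0.25), function(b) {
      nrow(detect_pulses(mk_series(y + b)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("summaries report frequency per hour and missing amplitude when empty", {
  y <- rep(c(1, 1, 1.5), 14)[1:41]  # 41 samples over 120 min
  calls <- detect_pulses(mk_series(y))
  sm <- summarize_pulses(calls, mk_series(y))
  expect_equal(sm$frequency_per_hour, sm$n_pulses / 2)
  empty <- detect_pulses(mk_series(c(3, 2, 1)))
  sme <- summarize_pulses(empty, mk_series(c(3, 2, 1)))
  expect_equal(sme$n_pulses, 0)
  expect_equal(sme$frequency_per_hour, 0)
  expect_true(is.na(sme$mean_amplitude))
  expect_true(is.na(sme$mean_ipi))
  expect_equal(sme$mean_lh, 2)
})

test_that("generator round trip recovers the inter-pulse interval", {
  ipis <- c()
  for (s in 1:8) {
    g <- generate_pulsatile(pulsatile_params(noise_cv = 0, seed = s))
    sm <- summarize_pulses(detect_pulses(g$series), g$series)
    ipis <- c(ipis, sm$interpulse_intervals)
  }
  expect_equal(mean(ipis), 15, tolerance = 0.10)
})

test_that("pulse sensitivity against secretion truth is at least 0.9", {
  hits <- 0; events <- 0
  for (s in 1:20) {
    g <- generate_pulsatile(pulsatile_params(noise_cv = 0.05, seed = s))
    calls <- detect_pulses(g$series)
    events_in_window <- g$truth$event_times[g$truth$event_times <= 117]
    events <- events + length(events_in_window)
    for (ev in events_in_window) {
      hits <- hits + any(calls$peak_time >= ev & calls$peak_time <= ev + 6)
    }
  }
  expect_gte(hits / events, 0.9)
})

test_that("surge classification keys on fold rise over the baseline sample", {
  flat <- data.frame(clock_hour = c(16, 19, 20, 21),
                     lh_ng_per_ml = rep(0.4, 4), animal_id = "t")
  cs <- classify_surge(flat)
  expect_equal(cs$fold_rise, 1.0)
  expect_false(cs$is_surge)
  surge <- classify_surge(generate_surge(surge_params(seed = 2)))
  expect_true(surge$is_surge)
  supp <- classify_surge(generate_surge(surge_params(seed = 2, noise_cv = 0,
                                                     suppressed = TRUE)))
  expect_false(supp$is_surge)
  expect_equal(supp$fold_rise, 1.0)
  # high fold rise from a tiny baseline still needs the absolute floor
  tiny <- data.frame(clock_hour = c(16, 19, 20, 21),
                     lh_ng_per_ml = c(0.05, 0.5, 0.4, 0.3), animal_id = "t")
  expect_false(classify_surge(tiny)$is_surge)
  expect_gt(classify_surge(tiny)$fold_rise, 2)
  expect_error(classify_surge(mk_series(1)), "at least 2")
})
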