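make_pulse_trace <- function(times, fs = 1000, dur = 10, amp = 5, seed = 1) {
  set.seed(seed)
  x <- 0.1 * rnorm(dur * fs)
  x[round(times * fs)] <- amp
  x
}

test_that("spike detection respects the refractory window", {
  x <- make_pulse_trace(c(2.000, 2.010), fs = 1000)
  expect_length(detect_spikes(x, 1000, spike_detect_params(refractory_s = 0.05)), 1)
  x2 <- make_pulse_trace(c(2.0, 2.2))
  expect_length(detect_spikes(x2, 1000, spike_detect_params(refractory_s = 0.05)), 2)
  expect_error(detect_spikes(rep(0, 1000), 1000), "flat")
})

test_that("detected spike times match simulated ground truth", {
  sim <- simulate_recording(sim_params(seed = 5, duration_s = 1500,
                                       csd_rate_per_hr = 0, epi_onset_s = 300,
                                       epi_escalation = "continuous"))
  x <- apply_filter(get_channel(sim$recording, "M1_left"), 300,
                    epi_filter_spec())
  d <- detect_spikes(x, 300)
  tt <- sim$truth$spike_times$M1_left
  precision <- mean(vapply(d, function(s) min(abs(tt - s)), 0) <= 0.05)
  recall <- mean(vapply(tt, function(s) min(abs(d - s)), 0) <= 0.05)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("bout grouping follows the gap and minimum-count definition", {
  p <- spike_detect_params(bout_max_gap_s = 2, bout_min_spikes = 3)
  b <- group_bouts(c(10, 10.5, 11, 100, 100.4, 100.9), p)
  expect_equal(b$start_s, c(10, 100))
  expect_equal(b$end_s, c(11, 100.9))
  expect_equal(nrow(group_bouts(c(5, 50), p)), 0)   # below minimum count
  expect_equal(nrow(group_bouts(numeric(0), p)), 0)
})

test_that("terminal activity classification distinguishes none, bouts and continuous", {
  p <- spike_detect_params()
  expect_equal(classify_activity(numeric(0), 3600, p), "none")
  cont <- seq(3000.5, 3599.5, by = 0.4)
  expect_equal(classify_activity(cont, 3600, p), "continuous")
  gappy <- cont[cont < 3300 | cont > 3310]          # 10 s interruption
  expect_equal(classify_activity(gappy, 3600, p), "bouts")
  early <- seq(100, 200, by = 0.4)                  # nothing in last 10 min
  expect_equal(classify_activity(early, 3600, p), "bouts")
})

test_that("onset is the earliest spike and is monotone under added spikes", {
  expect_equal(epileptiform_onset(c(840, 900, 1000)), 840)
  expect_true(is.na(epileptiform_onset(numeric(0))))
  st <- sort(runif(50, 500, 3000))
  expect_lte(epileptiform_onset(c(st, 400)), epileptiform_onset(st))
})

test_that("band power concentrates where the signal is", {
  fs <- 100
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  p_in <- band_power(x, fs, band = c(0.5, 4))
  p_out <- band_power(x, fs, band = c(10, 20))
  expect_gt(p_in, 100 * p_out)
  expect_equal(band_power(rep(0, length(t)), fs), 0)
  expect_error(band_power(x[1:100], fs), "segment")
})

test_that("white-noise band power is flat across equal-width bands", {
  set.seed(6)
  ratios <- replicate(20, {
    x <- rnorm(100 * 120)
    band_power(x, 100, band = c(5, 15)) / band_power(x, 100, band = c(25, 35))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.2)
})

test_that("severity follows the amplitude-squared scaling law exactly", {
  set.seed(7)
  fs <- 100
  w <- rnorm(600 * fs)
  x <- c(w, 2 * w)                     # last 10 min = first 10 min, doubled
  expect_equal(as.numeric(severity(x, fs)), 4, tolerance = 1e-9)
  expect_error(severity(w, fs), "at least")
  expect_error(severity(c(rep(0, 600 * fs), w), fs), "undefined-severity")
})

test_that("severity is invariant under a constant offset", {
  set.seed(8)
  x <- rnorm(100 * 1200)
  expect_equal(as.numeric(severity(x + 7, 100)), as.numeric(severity(x, 100)),
               tolerance = 1e-6)
})

test_that("generalization requires contralateral spikes with matching onset", {
  ann <- function(onset) structure(list(onset_s = onset), class = "epi_annotation")
  expect_true(is_generalized(ann(600), ann(610)))
  expect_false(is_generalized(ann(600), ann(NA_real_)))
  expect_false(is_generalized(ann(NA_real_), ann(NA_real_)))
  expect_false(is_generalized(ann(600), ann(900)))
})

test_that("annotation bundles the per-channel epileptiform read-out", {
  sim <- simulate_recording(sim_params(seed = 19, duration_s = 1500,
                                       csd_rate_per_hr = 0, epi_onset_s = 200,
                                       epi_escalation = "bouts"))
  x <- apply_filter(get_channel(sim$recording, "M1_left"), 300,
                    epi_filter_spec())
  ann <- annotate_epileptiform(x, 300, channel = "M1_left")
  expect_equal(ann$activity_class, "bouts")
  expect_equal(ann$onset_s, 200, tolerance = 30)
  expect_gt(nrow(ann$bouts), 0)
  expect_gt(ann$severity, 1)
})
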