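test_that("noise-only trace yields no CSD detections", {
  p <- sim_params(duration_s = 1800, csd_rate_per_hr = 0, epi_onset_s = NULL,
                  epi_escalation = "none", seed = 31)
  rec <- simulate_recording(p)$recording
  x <- apply_filter(get_channel(rec, "S1_left"), rec$fs, csd_filter_spec())
  ev <- detect_csds(x, rec$fs)
  expect_equal(nrow(ev), 0)
})

test_that("events are recovered with accurate onsets at default SNR", {
  for (seed in c(5, 17)) {
    sim <- simulate_recording(sim_params(seed = seed))
    rec <- sim$recording
    for (role in c("M1_left", "S1_left")) {
      x <- apply_filter(get_channel(rec, role), rec$fs, csd_filter_spec())
      ev <- detect_csds(x, rec$fs)
      truth <- sim$truth$csd_onsets[[role]]
      expect_equal(nrow(ev), length(truth))
      expect_lt(max(abs(ev$onset_s - truth)), 1)
      expect_true(all(ev$amplitude_mv < 0))
      expect_true(all(ev$onset_s < ev$trough_s))
      expect_true(all(ev$duration_s > 0))
    }
  }
})

test_that("events closer than the minimum separation merge into one", {
  fs <- 50
  t <- seq(0, 400 - 1 / fs, by = 1 / fs)
  set.seed(4)
  x <- 0.2 * rnorm(length(t)) +
    csd_waveform(t - 100, -10, 60) + csd_waveform(t - 190, -10, 60)
  spec50 <- filter_spec(0.005, 20, 2)
  ev <- detect_csds(apply_filter(x, fs, spec50), fs,
                    csd_detect_params(min_separation_s = 60))
  expect_equal(nrow(ev), 2)
  x2 <- 0.2 * rnorm(length(t)) +
    csd_waveform(t - 100, -10, 60) + csd_waveform(t - 130, -10, 60)
  ev2 <- detect_csds(apply_filter(x2, fs, spec50), fs,
                     csd_detect_params(min_separation_s = 60))
  expect_equal(nrow(ev2), 1)
})

test_that("detection is invariant under trace amplitude rescaling", {
  sim <- simulate_recording(sim_params(seed = 9, epi_escalation = "none",
                                       epi_onset_s = NULL,
                                       duration_s = 1800))
  x <- apply_filter(get_channel(sim$recording, "M1_left"), 300,
                    csd_filter_spec())
  ev1 <- detect_csds(x, 300)
  ev5 <- detect_csds(5 * x, 300)
  expect_equal(nrow(ev1), nrow(ev5))
  expect_equal(ev1$onset_s, ev5$onset_s, tolerance = 0.1)
})

test_that("unfiltered DC-dominated input raises a quality error", {
  set.seed(2)
  expect_error(detect_csds(50 + rnorm(10000), 100), "quality error")
  expect_error(detect_csds(rep(1, 10000), 100), "quality error")
})

test_that("CSD frequency follows the counting definition", {
  ev <- function(n) data.frame(onset_s = seq_len(n), trough_s = seq_len(n) + 1,
                               amplitude_mv = rep(-5, n),
                               duration_s = rep(20, n))
  expect_equal(csd_frequency(ev(12), 3600), 12)
  expect_equal(csd_frequency(ev(6), 1800), 12)
  expect_equal(csd_frequency(ev(0), 3600), 0)
})

test_that("propagation speed follows distance over first-onset difference", {
  ev <- function(on) data.frame(onset_s = on, trough_s = on + 10,
                                amplitude_mv = rep(-8, length(on)),
                                duration_s = rep(30, length(on)))
  expect_equal(propagation_speed(ev(100), ev(130)), 4)
  expect_equal(propagation_speed(ev(100), ev(124)), 5)
  expect_error(propagation_speed(ev(100), ev(100)), "undefined-speed")
  expect_error(propagation_speed(ev(numeric(0)), ev(100)), "undefined-speed")
  sp <- propagation_speed(ev(c(100, 300)), ev(c(124, 324)), per_event = TRUE)
  expect_equal(as.numeric(attr(sp, "per_event_speeds")), c(5, 5))
})

test_that("contralateral silence check reflects detected events", {
  empty <- data.frame(onset_s = numeric(0), trough_s = numeric(0),
                      amplitude_mv = numeric(0), duration_s = numeric(0))
  expect_true(assert_contralateral_silent(empty))
  expect_false(assert_contralateral_silent(
    data.frame(onset_s = 1, trough_s = 2, amplitude_mv = -5, duration_s = 20)))
})

test_that("csd_summary counts on the configured channel and flags contralateral events", {
  sim <- simulate_recording(sim_params(seed = 13, duration_s = 1800,
                                       epi_escalation = "none",
                                       epi_onset_s = NULL))
  cs <- csd_summary(sim$recording)
  expect_equal(cs$frequency_per_hr,
               length(sim$truth$csd_onsets$S1_left) * 2)
  expect_true(cs$contralateral_silent)
  expect_equal(cs$propagation_speed_mm_per_min, 5, tolerance = 0.05)
})
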