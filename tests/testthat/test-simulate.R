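test_that("CSD template has the canonical morphology", {
  t_dense <- seq(-5, 120, by = 0.005)
  w <- csd_waveform(t_dense, amplitude_mv = -10, duration_s = 60)
  expect_equal(min(w), -10, tolerance = 1e-6)        # trough = amplitude
  expect_equal(w[t_dense < 0], rep(0, sum(t_dense < 0)))
  expect_equal(w[t_dense > 60], rep(0, sum(t_dense > 60)))
  # unique trough
  i_min <- which(w < min(w) + 1e-9)
  expect_lt(diff(range(t_dense[i_min])), 0.02)
  # brief positive deflection before the trough, mild after-depolarization
  expect_gt(max(w[t_dense > 0 & t_dense < 6]), 0.5)
  expect_gt(max(w[t_dense > 50 & t_dense < 60]), 0)
  # finite integral
  expect_true(is.finite(sum(w) * 0.005))
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- sim_params(duration_s = 120, epi_onset_s = 20, csd_rate_per_hr = 30,
                  seed = 99)
  s1 <- simulate_recording(p)
  s2 <- simulate_recording(p)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth$csd_onsets, s2$truth$csd_onsets)
  expect_identical(s1$truth$spike_times, s2$truth$spike_times)
})

test_that("ground-truth onset lag between ipsilateral channels is d/speed exactly", {
  p <- sim_params(duration_s = 1200, propagation_speed_mm_per_min = 4,
                  epi_escalation = "none", epi_onset_s = NULL, seed = 3)
  tr <- simulate_recording(p)$truth
  expect_gt(length(tr$csd_onsets$M1_left), 0)
  expect_equal(tr$csd_onsets$S1_left - tr$csd_onsets$M1_left,
               rep(2 / (4 / 60), length(tr$csd_onsets$M1_left)))
  expect_length(tr$csd_onsets$M1_right, 0)
})

test_that("null process gives a noise-only recording with empty ground truth", {
  p <- sim_params(duration_s = 300, csd_rate_per_hr = 0, epi_onset_s = NULL,
                  epi_escalation = "none", seed = 12)
  sim <- simulate_recording(p)
  expect_length(sim$truth$csd_onsets$M1_left, 0)
  expect_length(sim$truth$spike_times$M1_left, 0)
  expect_equal(sd(sim$recording$data[, 1]), 0.5, tolerance = 0.01)
})

test_that("contralateral channel carries no CSD energy", {
  p <- sim_params(duration_s = 1200, noise_scale_mv = 0,
                  epi_escalation = "none", epi_onset_s = NULL, seed = 5)
  sim <- simulate_recording(p)
  expect_gt(max(abs(sim$recording$data[, "M1_left"])), 5)
  expect_equal(max(abs(sim$recording$data[, "M1_right"])), 0)
})

test_that("spikes start at the configured onset and are generalized with lags", {
  p <- sim_params(duration_s = 600, csd_rate_per_hr = 0, epi_onset_s = 100,
                  epi_escalation = "continuous", seed = 8)
  tr <- simulate_recording(p)$truth
  expect_equal(min(tr$spike_times$M1_left), 100)
  expect_true(all(tr$spike_times$M1_left >= 100))
  expect_gt(length(tr$spike_times$S1_left), 0)
  expect_gt(length(tr$spike_times$M1_right), 0)
  # M1_left leads on average by the configured lags
  expect_lt(abs(mean(tr$spike_times$S1_left) - mean(tr$spike_times$M1_left) -
                  p$intrahemispheric_lag_s), 2e-3)
})

test_that("severity growth raises the late/early band-power ratio of the spike component", {
  ratios <- vapply(c(1, 2, 3), function(g) {
    p <- sim_params(duration_s = 1500, csd_rate_per_hr = 0, epi_onset_s = 30,
                    epi_escalation = "continuous", noise_scale_mv = 0,
                    severity_growth = g, seed = 21)
    x <- simulate_recording(p)$recording$data[, "M1_left"]
    band_power(x, 300, 900, 1500) / band_power(x, 300, 0, 600)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("group presets encode the study's orderings", {
  groups <- c("male", "female", "aged_male", "PM_female")
  for (g in groups) {
    wt <- group_preset("WT", g)
    mu <- group_preset("G301R", g)
    expect_gt(mu$csd_rate_per_hr, wt$csd_rate_per_hr)
    expect_gt(mu$propagation_speed_mm_per_min, wt$propagation_speed_mm_per_min)
    expect_lt(mu$epi_onset_s, wt$epi_onset_s)
    expect_true(wt$epi_escalation %in% c("none", "bouts"))
  }
  pm <- group_preset("G301R", "PM_female")
  for (g in c("male", "female", "aged_male")) {
    expect_lt(pm$csd_rate_per_hr, group_preset("G301R", g)$csd_rate_per_hr)
  }
})

test_that("infeasible event packing warns and truncates", {
  p <- sim_params(duration_s = 600, csd_rate_per_hr = 80, csd_duration_s = 60,
                  epi_onset_s = NULL, epi_escalation = "none", seed = 2)
  expect_warning(sim <- simulate_recording(p), "truncated")
  on <- sim$truth$csd_onsets$M1_left
  expect_true(all(diff(on) >= 60))
})
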