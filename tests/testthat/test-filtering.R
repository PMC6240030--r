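test_that("SOS Butterworth design matches the reference design at moderate corners", {
  skip_if_not_installed("signal")
  f <- seq(1, 45, by = 0.5)
  for (cfg in list(list(n = 4, w = 0.3, type = "low"),
                   list(n = 3, w = 0.2, type = "high"),
                   list(n = 2, w = 0.05, type = "high"))) {
    sos <- csdscope:::butter_sos(cfg$n, cfg$w, cfg$type)
    h_mine <- abs(csdscope:::sos_freqz(sos, f, fs = 100))
    bt <- signal::butter(cfg$n, cfg$w, type = cfg$type)
    z <- exp(1i * 2 * pi * f / 100)
    h_ref <- abs(vapply(z, function(zz) {
      sum(bt$b * zz^-(seq_along(bt$b) - 1)) /
        sum(bt$a * zz^-(seq_along(bt$a) - 1))
    }, 0 + 0i))
    expect_equal(h_mine, h_ref, tolerance = 1e-8)
  }
})

test_that("high pass removes a DC offset and preserves in-band sines", {
  fs <- 300
  t <- seq(0, 30, by = 1 / fs)
  y <- apply_filter(rep(5, length(t)), fs, filter_spec(highpass_hz = 0.5, order = 2))
  expect_lt(max(abs(mean(y))), 0.01)

  x <- sin(2 * pi * 2 * t)
  y <- apply_filter(x, fs, epi_filter_spec())
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_equal(diff(range(y[mid])) / 2, 1, tolerance = 0.05)
})

test_that("low pass attenuates out-of-band sines by at least 20 dB", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * 200 * t)
  y <- apply_filter(x, fs, filter_spec(lowpass_hz = 100, order = 2))
  expect_lt(20 * log10(rms(y) / rms(x)), -20)
})

test_that("cutoffs outside (0, fs/2) are rejected", {
  expect_error(apply_filter(rnorm(100), 100, filter_spec(lowpass_hz = 60)),
               "outside")
  expect_error(filter_spec(highpass_hz = 10, lowpass_hz = 1))
  expect_error(filter_spec(highpass_hz = -1))
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(1)
  fs <- 300
  x <- cumsum(rnorm(3000)) / 10 + sin(2 * pi * 3 * seq_len(3000) / fs)
  for (spec in list(epi_filter_spec(), csd_filter_spec(),
                    filter_spec(lowpass_hz = 30, order = 4))) {
    y1 <- rev(apply_filter(rev(x), fs, spec))
    y2 <- apply_filter(x, fs, spec)
    expect_equal(y1, y2, tolerance = 1e-9)
  }
})

test_that("downsampling preserves duration and in-band amplitude, is idempotent", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- ecog_recording(cbind(sin(2 * pi * t), cos(2 * pi * t),
                              sin(2 * pi * 2 * t)), fs = fs)
  dn <- downsample(rec, 300)
  expect_equal(dn$fs, 300)
  expect_equal(recording_duration(dn), recording_duration(rec),
               tolerance = 1 / 300)
  mid <- 1000:2000
  expect_equal(diff(range(dn$data[mid, 1])) / 2, 1, tolerance = 0.01)
  expect_identical(downsample(dn, 300), dn)
  expect_error(downsample(dn, 500), "exceeds")
})

test_that("downsampling suppresses power near the new Nyquist by >= 20 dB", {
  set.seed(2)
  fs <- 1000
  rec <- ecog_recording(matrix(rnorm(3 * 20000), ncol = 3), fs = fs)
  dn <- downsample(rec, 300)
  sp <- welch_psd(dn$data[, 1], 300, seg_s = 5)
  pass <- mean(sp$psd[sp$freq >= 10 & sp$freq <= 100])
  stop_band <- mean(sp$psd[sp$freq >= 140])
  expect_lt(10 * log10(stop_band / pass), -20)
})
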