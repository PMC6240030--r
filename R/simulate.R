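# Synthetic awake-mouse ECoG with known ground truth.
#
# Emulates 1-hour, 3-channel DC-coupled recordings during occipital KCl
# application: quasi-periodic CSD events on the two ipsilateral channels
# (S1_left trailing M1_left by electrode distance / propagation speed),
# low-frequency epileptiform spike transients generalized across all three
# channels with small inter-channel lags, and 1/f background noise.

#' Simulation parameters
#'
#' Defaults describe a young adult G301R mouse: ~12 CSDs per hour at
#' 5 mm/min, epileptiform onset 10 minutes into the recording escalating to
#' continuous activity, on 1-hour 3-channel traces sampled at 300 Hz.
#' Group-level presets are in [group_preset()].
#'
#' @param duration_s Recording length, seconds.
#' @param fs Sampling rate, Hz.
#' @param csd_rate_per_hr Mean CSD event rate on the ipsilateral channels.
#'   Events form a renewal process: a refractory dead time of
#'   `csd_duration_s` plus a gamma(shape 8) interval, giving the
#'   quasi-periodic trains seen under continuous KCl application.
#' @param csd_amplitude_mv DC trough depth in mV (negative).
#' @param csd_duration_s Span of one depolarization-depression-recovery
#'   template, seconds.
#' @param propagation_speed_mm_per_min CSD wave speed between the two
#'   ipsilateral electrodes (2 mm apart).
#' @param epi_onset_s Time of the first epileptiform spike, or `NULL` for a
#'   subject that never develops epileptiform activity.
#' @param epi_escalation Terminal activity class the recording evolves
#'   toward: `"none"`, `"bouts"` or `"continuous"`.
#' @param spike_rate_hz Within-bout spike rate.
#' @param spike_amplitude_mv Spike transient peak amplitude (before the
#'   severity growth ramp).
#' @param interhemispheric_lag_s Spike lag of M1_right behind M1_left.
#' @param intrahemispheric_lag_s Spike lag of S1_left behind M1_left.
#' @param noise_scale_mv Standard deviation of the 1/f^alpha background.
#' @param noise_exponent Spectral exponent alpha of the background.
#' @param severity_growth Multiplier on spike amplitude at the end of the
#'   recording relative to onset (linear ramp); drives the late/early
#'   band-power severity ratio.
#' @param seed Integer seed; the same seed reproduces the recording
#'   bit for bit.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(duration_s = 3600, fs = 300,
                       csd_rate_per_hr = 12, csd_amplitude_mv = -10,
                       csd_duration_s = 60,
                       propagation_speed_mm_per_min = 5,
                       epi_onset_s = 600,
                       epi_escalation = c("continuous", "bouts", "none"),
                       spike_rate_hz = 2, spike_amplitude_mv = 3,
                       interhemispheric_lag_s = 0.025,
                       intrahemispheric_lag_s = 0.008,
                       noise_scale_mv = 0.5, noise_exponent = 1,
                       severity_growth = 2, seed = 1L) {
  epi_escalation <- match.arg(epi_escalation)
  stopifnot(duration_s > 0, fs > 0, csd_rate_per_hr >= 0,
            csd_amplitude_mv < 0, csd_duration_s > 0,
            interhemispheric_lag_s >= 0, intrahemispheric_lag_s >= 0,
            spike_rate_hz > 0, spike_amplitude_mv > 0,
            noise_scale_mv >= 0, severity_growth > 0)
  if (csd_rate_per_hr > 0) stopifnot(propagation_speed_mm_per_min > 0)
  if (!is.null(epi_onset_s)) stopifnot(epi_onset_s >= 0, epi_onset_s < duration_s)
  p <- list(duration_s = duration_s, fs = fs,
            csd_rate_per_hr = csd_rate_per_hr,
            csd_amplitude_mv = csd_amplitude_mv,
            csd_duration_s = csd_duration_s,
            propagation_speed_mm_per_min = propagation_speed_mm_per_min,
            epi_onset_s = epi_onset_s, epi_escalation = epi_escalation,
            spike_rate_hz = spike_rate_hz,
            spike_amplitude_mv = spike_amplitude_mv,
            interhemispheric_lag_s = interhemispheric_lag_s,
            intrahemispheric_lag_s = intrahemispheric_lag_s,
            noise_scale_mv = noise_scale_mv, noise_exponent = noise_exponent,
            severity_growth = severity_growth, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Group presets for the eight study cells
#'
#' Mean simulation parameters per genotype x group cell. Orderings follow
#' the study's findings: G301R mice have higher CSD rates and propagation
#' speeds and earlier epileptiform onset than wild types in every group;
#' post-menopausal G301R females have a lower CSD rate than the other G301R
#' groups but still above wild-type levels; wild types mostly show late
#' bouts at most. Magnitudes are free parameters chosen in the physiological
#' range (see the methods vignette for the calibration rationale).
#'
#' @param genotype `"WT"` or `"G301R"`.
#' @param group `"male"`, `"female"`, `"aged_male"` or `"PM_female"`.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A [sim_params()] object.
#' @export
group_preset <- function(genotype = c("WT", "G301R"),
                         group = c("male", "female", "aged_male", "PM_female"),
                         ...) {
  genotype <- match.arg(genotype)
  group <- match.arg(group)
  young <- group %in% c("male", "female")
  if (genotype == "WT") {
    base <- list(csd_rate_per_hr = 5, propagation_speed_mm_per_min = 3.5,
                 epi_onset_s = 2400, epi_escalation = "bouts",
                 severity_growth = 1.2)
  } else {
    base <- list(
      csd_rate_per_hr = if (group == "PM_female") 8.5 else 12,
      propagation_speed_mm_per_min = 5,
      epi_onset_s = switch(group, male = 700, female = 600,
                           aged_male = 700, PM_female = 1100),
      epi_escalation = if (young) "continuous" else "bouts",
      severity_growth = if (young) 2.5 else 1.8)
  }
  do.call(sim_params, utils::modifyList(base, list(...)))
}

# --- CSD waveform template -------------------------------------------------
# Unit shape in normalized time tau = t_rel / duration:
#  - brief positive deflection (the initial depolarizing wave front),
#  - steep drop into a deep negative trough (the DC shift),
#  - slow recovery with a mild positive after-depolarization.
# The shape is normalized so its minimum is exactly -1; template constants
# (trough time, 20%-depth onset crossing) are computed once on a dense grid.
csd_shape_raw <- function(tau) {
  pos <- 0.12 * exp(-((tau - 0.05) / 0.02)^2)
  edge <- 0.5 * (1 + tanh((tau - 0.10) / 0.012))
  recv <- exp(-(pmax(tau - 0.13, 0) / 0.45)^2)
  taper <- 0.5 * (1 + tanh((0.97 - tau) / 0.015))
  after <- 0.06 * exp(-((tau - 0.90) / 0.045)^2)
  out <- pos - edge * recv * taper + after
  out[tau < 0 | tau > 1] <- 0
  out
}

csd_template_env <- new.env(parent = emptyenv())

csd_template_constants <- function() {
  if (is.null(csd_template_env$const)) {
    tau <- seq(0, 1, length.out = 200001L)
    u <- csd_shape_raw(tau)
    i_min <- which.min(u)
    depth <- -u[i_min]
    # operational onset: last downward crossing of 20% of trough depth
    # before the trough (matches the detector's onset definition)
    below <- which(u[seq_len(i_min)] <= -0.2 * depth)
    i_on <- below[1L]
    # linear interpolation of the crossing
    x1 <- tau[i_on - 1L]; x2 <- tau[i_on]
    y1 <- u[i_on - 1L]; y2 <- u[i_on]
    tau_on <- x1 + (-0.2 * depth - y1) * (x2 - x1) / (y2 - y1)
    csd_template_env$const <- list(depth = depth, tau_trough = tau[i_min],
                                   tau_onset = tau_on)
  }
  csd_template_env$const
}

#' CSD waveform template
#'
#' Evaluates the canonical single-CSD DC waveform: a brief positive
#' deflection, a steep descent into a deep negative trough, then a slow
#' recovery with a mild after-depolarization. The template minimum equals
#' `amplitude_mv` exactly and the value is 0 outside `[0, duration_s]`.
#'
#' @param t_rel Time since template start, seconds (vectorized).
#' @param amplitude_mv Trough depth, mV (negative).
#' @param duration_s Template span, seconds.
#' @return Template values in mV.
#' @export
csd_waveform <- function(t_rel, amplitude_mv = -10, duration_s = 60) {
  stopifnot(amplitude_mv < 0, duration_s > 0)
  const <- csd_template_constants()
  (-amplitude_mv / const$depth) * csd_shape_raw(t_rel / duration_s)
}

# Onset offset (seconds from template start to the 20%-depth crossing).
csd_template_onset_offset <- function(duration_s) {
  csd_template_constants()$tau_onset * duration_s
}

# --- spike transient -------------------------------------------------------
# Biphasic low-frequency transient: a ~120 ms positive sharp wave followed
# by a slower negative wave, ~250 ms in total, so its spectral energy falls
# in the 0.5-4 Hz band that defines the severity statistic. Peak (positive
# lobe) = 1 at t = SPIKE_PEAK_OFFSET_S.
SPIKE_PEAK_OFFSET_S <- 0.07
SPIKE_TEMPLATE_SPAN_S <- 0.25

spike_template <- function(fs) {
  t <- seq(0, SPIKE_TEMPLATE_SPAN_S, by = 1 / fs)
  v <- exp(-((t - SPIKE_PEAK_OFFSET_S) / 0.025)^2) -
    0.45 * exp(-((t - 0.125) / 0.04)^2)
  v / max(v)
}

# Renewal event start times: dead time + gamma(shape) intervals.
draw_renewal_times <- function(rate_per_hr, dead_s, duration_s, shape = 8) {
  if (rate_per_hr <= 0) return(numeric(0))
  mean_gap <- 3600 / rate_per_hr
  ex <- mean_gap - dead_s
  if (ex <= 0) {
    warning("CSD rate and duration pack events beyond the refractory ",
            "period; events truncated to the dead-time spacing")
    ex <- 0.05 * dead_s
  }
  times <- numeric(0)
  t <- 30 + rgamma(1L, shape, shape / ex)
  while (t + dead_s <= duration_s) {
    times <- c(times, t)
    t <- t + dead_s + rgamma(1L, shape, shape / ex)
  }
  times
}

# Spike times of the master (M1_left) train. First spike exactly at onset.
draw_spike_train <- function(onset_s, duration_s, escalation, rate_hz) {
  if (is.null(onset_s) || escalation == "none") return(numeric(0))
  isi_shape <- 6
  draw_gaps <- function(n) rgamma(n, isi_shape, isi_shape * rate_hz)
  run_until <- function(t0, t1) {
    if (t1 <= t0) return(numeric(0))
    n_exp <- ceiling((t1 - t0) * rate_hz * 1.5) + 10L
    tt <- t0 + cumsum(c(0, draw_gaps(n_exp)))
    while (tt[length(tt)] < t1) tt <- c(tt, tt[length(tt)] + draw_gaps(50L))
    tt[tt <= t1]
  }
  spikes <- numeric(0)
  if (escalation == "continuous") {
    # bouts for the first 40% of the post-onset span, then gap-free firing
    esc_start <- onset_s + 0.4 * (duration_s - onset_s)
  } else {
    esc_start <- duration_s
  }
  t <- onset_s
  first <- TRUE
  while (t < esc_start) {
    bout_len <- rgamma(1L, 4, 4 / 8)
    spikes <- c(spikes, run_until(t, min(t + bout_len, esc_start)))
    gap <- 5 + rexp(1L, 1 / 40)
    t <- t + bout_len + gap
    if (first) first <- FALSE
  }
  if (escalation == "continuous") {
    spikes <- c(spikes, run_until(esc_start, duration_s - 0.2))
  }
  sort(unique(spikes))
}

#' Simulate a recording with known ground truth
#'
#' Builds a 3-channel recording from a [sim_params()]: CSD templates on
#' M1_left and S1_left only (S1 delayed by electrode distance / speed, the
#' contralateral M1_right carries no CSD energy), epileptiform spikes on all
#' three channels after `epi_onset_s` with M1_left leading, and additive
#' 1/f^alpha noise. Returns the recording together with the true event
#' times used to build it.
#'
#' @param params A [sim_params()].
#' @param subject A [subject_meta()] attached to the recording.
#' @return List with elements `recording` (an [ecog_recording()]) and
#'   `truth` (class `ground_truth`: per-channel `csd_onsets`, per-channel
#'   `spike_times`, and `true_params`).
#' @export
simulate_recording <- function(params = sim_params(),
                               subject = subject_meta()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  fs <- params$fs
  n <- round(params$duration_s * fs)
  dur <- params$duration_s

  # --- 1/f^alpha background noise ---
  # One length-n FFT of a spectrally shaped complex Gaussian sequence (no
  # Hermitian symmetry) yields two independent real 1/f channels in its
  # real and imaginary parts.
  noise_pair <- function() {
    f <- (0:(n - 1L)) / n * fs
    f <- pmin(f, fs - f)                   # two-sided frequency magnitudes
    shape_amp <- pmax(f, 0.01)^(-params$noise_exponent / 2)
    shape_amp[1L] <- 0
    z <- complex(real = rnorm(n), imaginary = rnorm(n)) * shape_amp
    w <- fft(z, inverse = TRUE) / sqrt(n)
    sc <- params$noise_scale_mv
    list(Re(w) * sc / stats::sd(Re(w)), Im(w) * sc / stats::sd(Im(w)))
  }
  make_noise_all <- function(k) {
    if (params$noise_scale_mv == 0) {
      return(replicate(k, numeric(n), simplify = FALSE))
    }
    out <- list()
    while (length(out) < k) out <- c(out, noise_pair())
    out[seq_len(k)]
  }

  chans <- list(M1_left = numeric(n), S1_left = numeric(n),
                M1_right = numeric(n))

  # --- CSD events (ipsilateral channels only) ---
  csd_lag <- ELECTRODE_DISTANCE_MM /
    (params$propagation_speed_mm_per_min / 60)     # s between M1L and S1L
  csd_starts <- draw_renewal_times(params$csd_rate_per_hr,
                                   params$csd_duration_s, dur)
  csd_starts <- csd_starts[csd_starts + csd_lag + params$csd_duration_s <= dur]
  tmpl_t <- seq(0, params$csd_duration_s, by = 1 / fs)
  csd_tmpl <- csd_waveform(tmpl_t, params$csd_amplitude_mv,
                           params$csd_duration_s)
  if (length(csd_starts)) {
    for (role in c("M1_left", "S1_left")) {
      lag <- if (role == "S1_left") csd_lag else 0
      at <- as.integer(round((csd_starts + lag) * fs))
      chans[[role]] <- add_events_cpp(chans[[role]], csd_tmpl, at,
                                      rep(1, length(at)))
    }
  }
  onset_off <- csd_template_onset_offset(params$csd_duration_s)
  truth_csd <- list(
    M1_left = csd_starts + onset_off,
    S1_left = csd_starts + onset_off + csd_lag,
    M1_right = numeric(0))

  # --- epileptiform spikes, generalized across hemispheres ---
  master <- draw_spike_train(params$epi_onset_s, dur, params$epi_escalation,
                             params$spike_rate_hz)
  truth_spikes <- list(M1_left = numeric(0), S1_left = numeric(0),
                       M1_right = numeric(0))
  if (length(master)) {
    # amplitude growth ramp driving the late/early severity ratio
    ramp <- 1 + (params$severity_growth - 1) *
      (master - params$epi_onset_s) / max(dur - params$epi_onset_s, 1)
    lags <- c(M1_left = 0, S1_left = params$intrahemispheric_lag_s,
              M1_right = params$interhemispheric_lag_s)
    jit_sd <- c(M1_left = 0, S1_left = 0.002, M1_right = 0.004)
    sp_tmpl <- spike_template(fs)
    # during bouts-stage activity, spikes are confined to the post-trough
    # phase of a CSD; once continuous they ride through the whole event
    suppress <- function(times) {
      if (params$epi_escalation == "continuous" || !length(csd_starts)) {
        return(rep(FALSE, length(times)))
      }
      bad <- rep(FALSE, length(times))
      for (s in csd_starts) {
        bad <- bad | (times > s & times < s + 0.6 * params$csd_duration_s)
      }
      bad
    }
    for (role in names(chans)) {
      tt <- master + lags[[role]] +
        if (jit_sd[[role]] > 0) rnorm(length(master), 0, jit_sd[[role]]) else 0
      amp <- params$spike_amplitude_mv * ramp *
        rlnorm(length(master), 0, 0.15)
      keep <- !suppress(tt) & tt >= 0 &
        tt + SPIKE_TEMPLATE_SPAN_S < dur
      tt <- tt[keep]; amp <- amp[keep]
      ord <- order(tt)
      tt <- tt[ord]; amp <- amp[ord]
      at <- as.integer(round((tt - SPIKE_PEAK_OFFSET_S) * fs))
      chans[[role]] <- add_events_cpp(chans[[role]], sp_tmpl, at, amp)
      truth_spikes[[role]] <- tt
    }
  }

  noi <- make_noise_all(length(chans))
  for (j in seq_along(chans)) chans[[j]] <- chans[[j]] + noi[[j]]

  rec <- ecog_recording(chans, fs = fs, channels = names(chans),
                        t0 = 0, subject = subject)
  truth <- structure(list(csd_onsets = truth_csd, spike_times = truth_spikes,
                          true_params = params),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Serialize ground truth to JSON
#'
#' @param truth A `ground_truth` object from [simulate_recording()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$true_params
  p$epi_onset_s <- if (is.null(p$epi_onset_s)) NA else p$epi_onset_s
  jsonlite::write_json(
    list(csd_onsets = truth$csd_onsets, spike_times = truth$spike_times,
         true_params = unclass(p)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
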