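# CSD detection on the DC-filtered trace (0.005 Hz high pass, 100 Hz low
# pass). A CSD appears as a large, sustained negative shift of the DC
# potential: an initial depolarizing wave front, a deep trough, and a slow
# recovery. The detector is threshold-based with a robust (MAD) spread
# estimate so it is invariant under trace amplitude rescaling.

#' CSD detection parameters
#'
#' @param amp_threshold Trough threshold as a multiple of the MAD-based
#'   spread of the DC trace.
#' @param floor_mv Absolute threshold floor in mV; the effective threshold
#'   is `max(amp_threshold * spread, floor_mv)`.
#' @param min_duration_s Minimum sustained sub-threshold span for an event.
#' @param min_separation_s Events closer than this are merged into one.
#' @param onset_fraction Fraction of the trough depth whose last crossing
#'   before the trough defines the event onset.
#' @return Object of class `csd_detect_params`.
#' @export
csd_detect_params <- function(amp_threshold = 8, floor_mv = 2,
                              min_duration_s = 10, min_separation_s = 60,
                              onset_fraction = 0.2) {
  stopifnot(amp_threshold > 0, floor_mv > 0, min_duration_s > 0,
            min_separation_s > 0, onset_fraction > 0, onset_fraction < 1)
  structure(list(amp_threshold = amp_threshold, floor_mv = floor_mv,
                 min_duration_s = min_duration_s,
                 min_separation_s = min_separation_s,
                 onset_fraction = onset_fraction),
            class = "csd_detect_params")
}

#' Detect CSD events in a DC-filtered trace
#'
#' Finds sustained negative DC shifts: samples below
#' `-max(amp_threshold * spread, floor_mv)` are grouped into runs, runs
#' closer than `min_separation_s` are merged, and runs sustained for less
#' than `min_duration_s` are discarded. For each event the trough is the
#' minimum sample; the onset is the last crossing of
#' `onset_fraction * depth` before the trough (linearly interpolated
#' between samples); the duration runs from onset to the first recovery
#' above that level after the trough.
#'
#' @param trace_dc DC-chain filtered trace (mV); see [csd_filter_spec()].
#' @param fs Sampling rate, Hz.
#' @param params A [csd_detect_params()].
#' @param t0 Time of the first sample, seconds.
#' @return `data.frame` of class `csd_events` with columns `onset_s`,
#'   `trough_s`, `amplitude_mv` (negative trough depth) and `duration_s`,
#'   sorted by onset. The threshold used is attached as attribute
#'   `threshold_mv`.
#' @export
detect_csds <- function(trace_dc, fs, params = csd_detect_params(), t0 = 0) {
  stopifnot(inherits(params, "csd_detect_params"), fs > 0)
  x <- as.numeric(trace_dc)
  # Detection trace: an extra zero-phase 0.5 Hz low pass suppresses
  # epileptiform spike transients riding on the DC shift (their energy is
  # at 0.5-4 Hz and above) by >40 dB while leaving the CSD waveform, whose
  # energy sits below ~0.1 Hz, essentially untouched. Zero phase keeps
  # onset timing unbiased.
  if (0.5 < fs / 2 && length(x) > 24) {
    x <- sos_filtfilt(x, butter_sos(2L, 0.5 / (fs / 2), "low"))
  }
  # spread estimates on a stride subsample: statistically equivalent for
  # thresholding, much cheaper on hour-long traces
  stride <- max(1L, length(x) %/% 250000L)
  xs <- x[seq(1L, length(x), by = stride)]
  med <- stats::median(xs)
  spread <- stats::mad(xs)
  if (!is.finite(spread) || spread <= .Machine$double.eps) {
    stop("quality error: degenerate baseline spread (flat trace?)")
  }
  if (abs(med) > 5 * spread) {
    stop("quality error: trace is DC-offset dominated; ",
         "apply the 0.005 Hz high-pass chain before detection")
  }
  # Two-pass baseline spread: a first provisional threshold masks candidate
  # events (plus a margin for the recovery tail), then the spread is
  # re-estimated from the event-free baseline so that high CSD rates do not
  # inflate the threshold.
  thr0 <- max(params$amp_threshold * spread, params$floor_mv)
  mask <- (x - med) < -thr0
  if (any(mask)) {
    margin <- round(30 * fs)
    r0 <- rle(mask)
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1L
    covered <- logical(length(x))
    for (k in which(r0$values)) {
      covered[max(s0[k] - margin, 1L):min(e0[k] + margin, length(x))] <- TRUE
    }
    if (mean(covered) < 0.8) {
      base <- x[!covered]
      base <- base[seq(1L, length(base), by = stride)]
      med <- stats::median(base)
      spread <- stats::mad(base)
    }
  }
  thr <- max(params$amp_threshold * spread, params$floor_mv)
  dev <- x - med
  below <- dev < -thr
  empty <- structure(
    data.frame(onset_s = numeric(0), trough_s = numeric(0),
               amplitude_mv = numeric(0), duration_s = numeric(0)),
    class = c("csd_events", "data.frame"), threshold_mv = thr)
  if (!any(below)) return(empty)

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than min_separation_s
  gap_samp <- params$min_separation_s * fs
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1L] - merged[nrow(merged), 2L] < gap_samp) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  # sustained-deflection criterion: total sub-threshold time in the event
  below_s <- vapply(seq_len(nrow(merged)), function(k) {
    sum(below[merged[k, 1L]:merged[k, 2L]]) / fs
  }, 0)
  merged <- merged[below_s >= params$min_duration_s, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)

  cross_back <- function(i_tr, level) {
    # last sample before the trough at or above `level`
    i <- i_tr
    while (i > 1L && dev[i] < level) i <- i - 1L
    if (dev[i] < level) return(i)           # ran into the trace start
    # interpolate the downward crossing between i and i+1
    i + (level - dev[i]) / (dev[i + 1L] - dev[i])
  }
  cross_fwd <- function(i_tr, level) {
    n <- length(dev)
    i <- i_tr
    while (i < n && dev[i] < level) i <- i + 1L
    if (dev[i] < level) return(i)
    (i - 1L) + (level - dev[i - 1L]) / (dev[i] - dev[i - 1L])
  }
  ev <- lapply(seq_len(nrow(merged)), function(k) {
    seg <- merged[k, 1L]:merged[k, 2L]
    i_tr <- seg[which.min(dev[seg])]
    depth <- dev[i_tr]
    level <- params$onset_fraction * depth       # negative level
    i_on <- cross_back(i_tr, level)
    i_off <- cross_fwd(i_tr, level)
    data.frame(onset_s = t0 + (i_on - 1) / fs,
               trough_s = t0 + (i_tr - 1) / fs,
               amplitude_mv = depth,
               duration_s = (i_off - i_on) / fs)
  })
  out <- do.call(rbind, ev)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("csd_events", "data.frame"), threshold_mv = thr)
}

#' CSD frequency in events per hour
#'
#' @param events A `csd_events` frame (or anything with `nrow`).
#' @param duration_s Recording duration, seconds.
#' @return Events per hour.
#' @export
csd_frequency <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  nrow(events) * 3600 / duration_s
}

#' CSD propagation speed between the ipsilateral electrodes
#'
#' Speed is the electrode distance divided by the difference in onset of the
#' depolarizing wave of the first CSD on the two ipsilateral channels,
#' expressed in mm/min. With `per_event = TRUE` a per-event speed vector
#' (events paired in order) is returned as well.
#'
#' @param events_m1,events_s1 `csd_events` for M1_left and S1_left.
#' @param distance_mm Electrode distance, mm.
#' @param min_dt_s Onset differences below this (one sample by default) are
#'   treated as undefined.
#' @param per_event Also compute speeds for all pairable events.
#' @return Speed in mm/min; with `per_event`, attribute `per_event_speeds`.
#' @export
propagation_speed <- function(events_m1, events_s1,
                              distance_mm = ELECTRODE_DISTANCE_MM,
                              min_dt_s = 1 / 300, per_event = FALSE) {
  stopifnot(distance_mm > 0)
  if (nrow(events_m1) == 0L || nrow(events_s1) == 0L) {
    stop("undefined-speed error: need at least one CSD on each ipsilateral channel")
  }
  dt <- abs(events_s1$onset_s[1L] - events_m1$onset_s[1L])
  if (dt < min_dt_s) {
    stop("undefined-speed error: onset difference below one sample")
  }
  speed <- distance_mm / dt * 60
  if (per_event) {
    m <- min(nrow(events_m1), nrow(events_s1))
    dts <- abs(events_s1$onset_s[seq_len(m)] - events_m1$onset_s[seq_len(m)])
    attr(speed, "per_event_speeds") <- ifelse(dts >= min_dt_s,
                                              distance_mm / dts * 60, NA_real_)
  }
  speed
}

#' Check that the contralateral channel is CSD-silent
#'
#' CSDs remain confined to the hemisphere of the KCl application; any event
#' detected on M1_right indicates either true contralateral spread or a
#' detection artifact.
#'
#' @param events_contra `csd_events` detected on the contralateral channel.
#' @return `TRUE` iff no events were detected.
#' @export
assert_contralateral_silent <- function(events_contra) {
  nrow(events_contra) == 0L
}

#' Per-recording CSD summary
#'
#' Runs the DC chain and CSD detection on the ipsilateral channels (plus the
#' contralateral control), and summarizes frequency and propagation speed.
#' Frequency is counted on `counting_channel` (S1_left by default, the
#' electrode nearest the KCl application site).
#'
#' @param rec An [ecog_recording()].
#' @param params A [csd_detect_params()].
#' @param counting_channel Channel whose event count defines the frequency.
#' @param filter A [filter_spec()] for the DC chain.
#' @return List of class `csd_summary`: `frequency_per_hr`,
#'   `propagation_speed_mm_per_min` (NA when undefined), `n_events` per
#'   channel, `contralateral_silent`, and the per-channel `events`.
#' @export
csd_summary <- function(rec, params = csd_detect_params(),
                        counting_channel = "S1_left",
                        filter = csd_filter_spec()) {
  stopifnot(inherits(rec, "ecog_recording"))
  ev <- lapply(rec$channels, function(role) {
    detect_csds(apply_filter(get_channel(rec, role), rec$fs,
                             adapt_spec(filter, rec$fs)),
                rec$fs, params, t0 = rec$t0)
  })
  names(ev) <- rec$channels
  dur <- recording_duration(rec)
  speed <- tryCatch(propagation_speed(ev$M1_left, ev$S1_left),
                    error = function(e) NA_real_)
  structure(list(
    frequency_per_hr = csd_frequency(ev[[counting_channel]], dur),
    propagation_speed_mm_per_min = as.numeric(speed),
    n_events = vapply(ev, nrow, 0L),
    contralateral_silent = if ("M1_right" %in% names(ev))
      assert_contralateral_silent(ev$M1_right) else NA,
    events = ev), class = "csd_summary")
}

#' @export
print.csd_summary <- function(x, ...) {
  cat(sprintf("<csd_summary> %.2f CSD/hr, speed %.2f mm/min\n",
              x$frequency_per_hr, x$propagation_speed_mm_per_min))
  cat("  events:", paste(names(x$n_events), x$n_events, sep = "=",
                         collapse = ", "),
      "| contralateral silent:", x$contralateral_silent, "\n")
  invisible(x)
}
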