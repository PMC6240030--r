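# Epileptiform analysis on the 0.5 Hz high-passed trace: threshold spike
# picking with a refractory window, grouping into bouts, terminal activity
# classification (none / bouts / continuous), onset, generalization across
# hemispheres, and the band-power severity score (0.5-4 Hz power in the
# last 10 minutes normalized to the first 10 minutes).

#' Spike detection parameters
#'
#' @param amp_threshold Threshold as a multiple of the MAD-based spread
#'   (consistent sigma estimate) of the filtered trace.
#' @param refractory_s Minimum time between two detected spikes.
#' @param bout_max_gap_s Maximum inter-spike gap within one bout.
#' @param bout_min_spikes Minimum spikes for a run to count as a bout.
#' @param continuous_max_gap_s Maximum tolerated gap for activity to count
#'   as continuous over the terminal window.
#' @param class_window_s Terminal window assessed for the activity class.
#' @return Object of class `spike_detect_params`.
#' @export
spike_detect_params <- function(amp_threshold = 5, refractory_s = 0.05,
                                bout_max_gap_s = 2, bout_min_spikes = 3,
                                continuous_max_gap_s = 2,
                                class_window_s = 600) {
  stopifnot(amp_threshold > 0, refractory_s > 0, bout_max_gap_s > 0,
            bout_min_spikes >= 1, continuous_max_gap_s > 0,
            class_window_s > 0,
            continuous_max_gap_s <= bout_max_gap_s)
  structure(list(amp_threshold = amp_threshold, refractory_s = refractory_s,
                 bout_max_gap_s = bout_max_gap_s,
                 bout_min_spikes = bout_min_spikes,
                 continuous_max_gap_s = continuous_max_gap_s,
                 class_window_s = class_window_s),
            class = "spike_detect_params")
}

#' Detect epileptiform spikes
#'
#' Flags absolute deflections beyond `amp_threshold` times the robust
#' spread of the high-passed trace, keeps the largest deflection per
#' suprathreshold cluster, and enforces the refractory window.
#'
#' @param trace_hp Epileptiform-chain filtered trace (mV); see
#'   [epi_filter_spec()].
#' @param fs Sampling rate, Hz.
#' @param params A [spike_detect_params()].
#' @param t0 Time of the first sample, seconds.
#' @return Sorted spike times in seconds.
#' @export
detect_spikes <- function(trace_hp, fs, params = spike_detect_params(),
                          t0 = 0) {
  stopifnot(inherits(params, "spike_detect_params"), fs > 0)
  x <- as.numeric(trace_hp)
  stride <- max(1L, length(x) %/% 250000L)
  xs <- x[seq(1L, length(x), by = stride)]
  spread <- stats::mad(xs)
  if (!is.finite(spread) || spread <= .Machine$double.eps) {
    stop("quality error: flat trace (zero spread)")
  }
  thr <- params$amp_threshold * spread
  a <- abs(x - stats::median(xs))
  cand <- which(a > thr)
  if (!length(cand)) return(numeric(0))
  refr <- params$refractory_s * fs
  # cluster candidate samples closer than the refractory window
  grp <- cumsum(c(1L, diff(cand) > refr))
  peaks <- vapply(split(cand, grp),
                  function(ix) ix[which.max(a[ix])], 0L)
  peaks <- sort(unname(peaks))
  # a long cluster can still yield peaks closer than the refractory window
  keep <- peaks[1L]
  for (p in peaks[-1L]) {
    if (p - keep[length(keep)] > refr) keep <- c(keep, p)
  }
  t0 + (keep - 1L) / fs
}

#' Group spikes into bouts
#'
#' A bout is a maximal run of at least `bout_min_spikes` spikes whose
#' consecutive gaps do not exceed `bout_max_gap_s`; its span runs from the
#' first to the last spike of the run.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param params A [spike_detect_params()].
#' @return `data.frame` with columns `start_s`, `end_s`, `n_spikes`.
#' @export
group_bouts <- function(spike_times, params = spike_detect_params()) {
  st <- sort(as.numeric(spike_times))
  if (!length(st)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0)))
  }
  grp <- cumsum(c(1L, diff(st) > params$bout_max_gap_s))
  runs <- split(st, grp)
  runs <- runs[lengths(runs) >= params$bout_min_spikes]
  data.frame(start_s = vapply(runs, min, 0),
             end_s = vapply(runs, max, 0),
             n_spikes = lengths(runs), row.names = NULL)
}

#' Classify terminal epileptiform activity
#'
#' `"none"` if the recording holds no spikes; `"continuous"` if, over the
#' terminal `class_window_s`, spiking spans the whole window with no gap
#' exceeding `continuous_max_gap_s`; otherwise `"bouts"`.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param duration_s Recording duration, seconds.
#' @param params A [spike_detect_params()].
#' @return One of `"none"`, `"bouts"`, `"continuous"`.
#' @export
classify_activity <- function(spike_times, duration_s,
                              params = spike_detect_params()) {
  st <- sort(as.numeric(spike_times))
  if (!length(st)) return("none")
  w0 <- max(duration_s - params$class_window_s, 0)
  sw <- st[st >= w0]
  g <- params$continuous_max_gap_s
  if (length(sw) >= 2L &&
      (sw[1L] - w0) <= g &&
      (duration_s - sw[length(sw)]) <= g &&
      max(diff(sw)) <= g) {
    return("continuous")
  }
  "bouts"
}

#' Onset of epileptiform activity
#'
#' The first moment at which clearly distinguishable spikes occur, i.e. the
#' earliest detected spike time.
#'
#' @param spike_times Spike times, seconds.
#' @return Onset in seconds, or `NA_real_` when there are no spikes.
#' @export
epileptiform_onset <- function(spike_times) {
  if (!length(spike_times)) return(NA_real_)
  min(spike_times)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-tapered segments of `seg_s` seconds
#' with 50% overlap, one-sided density in mV^2/Hz.
#'
#' @param x Trace (mV).
#' @param fs Sampling rate, Hz.
#' @param seg_s Segment length, seconds.
#' @param overlap Fractional overlap between segments.
#' @return `data.frame` with columns `freq` (Hz) and `psd` (mV^2/Hz);
#'   attributes `seg_s`, `overlap`, `n_segments`.
#' @export
welch_psd <- function(x, fs, seg_s = 30, overlap = 0.5) {
  x <- as.numeric(x)
  L <- round(seg_s * fs)
  if (length(x) < L) {
    stop("window shorter than one segment (", seg_s, " s)")
  }
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann taper
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- Mod(fft(seg)[seq_len(nf)])^2 / scale
    acc <- acc + p
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]   # one-sided
  out <- data.frame(freq = seq(0, fs / 2, length.out = nf), psd = psd)
  attr(out, "seg_s") <- seg_s
  attr(out, "overlap") <- overlap
  attr(out, "n_segments") <- length(starts)
  out
}

#' Mean band power of a trace window
#'
#' Average power spectral density over `band` computed from a Welch
#' spectrum of `trace[t_start, t_stop]`.
#'
#' @param trace Trace (mV).
#' @param fs Sampling rate, Hz.
#' @param t_start,t_stop Window bounds in seconds (relative to the first
#'   sample).
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param seg_s Welch segment length, seconds.
#' @return Mean density in the band, mV^2/Hz.
#' @export
band_power <- function(trace, fs, t_start = 0,
                       t_stop = length(trace) / fs, band = c(0.5, 4),
                       seg_s = 30) {
  stopifnot(t_stop > t_start, band[1] >= 0, band[2] > band[1],
            band[2] < fs / 2)
  i0 <- max(1L, floor(t_start * fs) + 1L)
  i1 <- min(length(trace), floor(t_stop * fs))
  sp <- welch_psd(trace[i0:i1], fs, seg_s = seg_s)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  mean(sp$psd[sel])
}

#' Band-power severity of epileptiform activity
#'
#' Mean 0.5-4 Hz power in the last `window_s` of the trace normalized to
#' the mean power in that band over the first `window_s`. A value near 1
#' indicates no change; escalating spike activity drives the ratio up as
#' the square of the amplitude growth.
#'
#' @param trace_hp Epileptiform-chain filtered trace (mV).
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording duration, seconds (defaults to the trace
#'   length); must be at least `2 * window_s`.
#' @param band Frequency band, Hz.
#' @param window_s Window length, seconds (10 minutes by default).
#' @return Severity ratio (dimensionless). Attribute `windows` records the
#'   two windows used; attribute `early_abort` flags recordings shorter
#'   than a full hour.
#' @export
severity <- function(trace_hp, fs, duration_s = length(trace_hp) / fs,
                     band = c(0.5, 4), window_s = 600) {
  if (duration_s < 2 * window_s) {
    stop("severity needs at least ", 2 * window_s, " s of recording")
  }
  first <- band_power(trace_hp, fs, 0, window_s, band)
  last <- band_power(trace_hp, fs, duration_s - window_s, duration_s, band)
  if (first <= 0) stop("undefined-severity error: first-window power is zero")
  out <- last / first
  attr(out, "windows") <- c(first_start = 0, first_stop = window_s,
                            last_start = duration_s - window_s,
                            last_stop = duration_s)
  attr(out, "early_abort") <- duration_s < 3600
  out
}

#' Per-channel epileptiform annotation
#'
#' Runs spike detection, bout grouping, onset, terminal classification and
#' (when the trace is long enough) the severity score on one filtered
#' channel.
#'
#' @param trace_hp Epileptiform-chain filtered trace (mV).
#' @param fs Sampling rate, Hz.
#' @param params A [spike_detect_params()].
#' @param channel Channel role label carried in the result.
#' @return List of class `epi_annotation`: `channel`, `spike_times_s`,
#'   `bouts`, `onset_s`, `activity_class`, `severity`.
#' @export
annotate_epileptiform <- function(trace_hp, fs,
                                  params = spike_detect_params(),
                                  channel = NA_character_) {
  dur <- length(trace_hp) / fs
  st <- detect_spikes(trace_hp, fs, params)
  sev <- if (dur >= 1200) {
    tryCatch(severity(trace_hp, fs, dur), error = function(e) NA_real_)
  } else NA_real_
  structure(list(channel = channel, spike_times_s = st,
                 bouts = group_bouts(st, params),
                 onset_s = epileptiform_onset(st),
                 activity_class = classify_activity(st, dur, params),
                 severity = as.numeric(sev)),
            class = "epi_annotation")
}

#' @export
print.epi_annotation <- function(x, ...) {
  cat(sprintf("<epi_annotation> %s: %d spikes, %d bouts, class %s\n",
              x$channel, length(x$spike_times_s), nrow(x$bouts),
              x$activity_class))
  cat(sprintf("  onset %.1f s, severity %.3g\n", x$onset_s, x$severity))
  invisible(x)
}

#' Is epileptiform activity generalized across hemispheres?
#'
#' Activity counts as generalized when the contralateral channel also shows
#' spikes and its onset falls within `tol_s` of the ipsilateral onset.
#'
#' @param epi_ipsi,epi_contra [annotate_epileptiform()] results for the
#'   ipsilateral and contralateral channels.
#' @param tol_s Onset agreement tolerance, seconds.
#' @return Logical.
#' @export
is_generalized <- function(epi_ipsi, epi_contra, tol_s = 60) {
  on_i <- epi_ipsi$onset_s
  on_c <- epi_contra$onset_s
  if (is.na(on_i) || is.na(on_c)) return(FALSE)
  abs(on_c - on_i) <= tol_s
}
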