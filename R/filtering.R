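#' Filter specification for offline ECoG conditioning
#'
#' Bundles the high-pass/low-pass corner frequencies and Butterworth order
#' used by the two analysis chains: the DC chain (0.005 Hz high pass) that
#' preserves the slow negative potential shift of a cortical spreading
#' depression, and the epileptiform chain (0.5 Hz high pass) that removes the
#' DC shift so low-frequency spike transients stand out. A 100 Hz low pass is
#' applied in both chains.
#'
#' @param highpass_hz High-pass corner in Hz, or `NULL` for none.
#' @param lowpass_hz Low-pass corner in Hz, or `NULL` for none.
#' @param order Butterworth order per stage (the zero-phase composition
#'   doubles the effective magnitude order).
#' @return An object of class `filter_spec`.
#' @seealso [apply_filter()], [csd_filter_spec()], [epi_filter_spec()]
#' @export
filter_spec <- function(highpass_hz = NULL, lowpass_hz = NULL, order = 2L) {
  if (!is.null(highpass_hz)) {
    stopifnot(is.numeric(highpass_hz), length(highpass_hz) == 1L, highpass_hz > 0)
  }
  if (!is.null(lowpass_hz)) {
    stopifnot(is.numeric(lowpass_hz), length(lowpass_hz) == 1L, lowpass_hz > 0)
  }
  if (!is.null(highpass_hz) && !is.null(lowpass_hz) && highpass_hz >= lowpass_hz) {
    stop("highpass_hz must be below lowpass_hz")
  }
  stopifnot(order >= 1L)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
csd_filter_spec <- function(order = 2L) filter_spec(0.005, 100, order)

#' @rdname filter_spec
#' @export
epi_filter_spec <- function(order = 2L) filter_spec(0.5, 100, order)

# Drop a low-pass stage that sits at or above the trace's Nyquist: such a
# trace is already bandlimited below the cutoff.
adapt_spec <- function(spec, fs) {
  if (!is.null(spec$lowpass_hz) && spec$lowpass_hz >= fs / 2) {
    spec$lowpass_hz <- NULL
  }
  spec
}

#' Butterworth design as second-order sections
#'
#' Designs the filter in zero-pole-gain form (analog prototype poles, warped
#' corner, bilinear transform) and only then groups conjugate pole pairs into
#' biquads. This stays numerically well conditioned at extreme corners such
#' as 0.005 Hz on a 300 Hz trace, where an expanded transfer-function
#' polynomial loses all precision.
#'
#' @param order Filter order (>= 1).
#' @param w Corner as a fraction of the Nyquist frequency, in (0, 1).
#' @param type `"low"` or `"high"`.
#' @return Matrix with one row per section, columns `b0 b1 b2 a0 a1 a2`.
#' @keywords internal
butter_sos <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, w > 0, w < 1)
  wa <- tan(pi * w / 2)                      # pre-warped analog corner
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP prototype poles
  p <- if (type == "low") wa * p else wa / p
  zd <- (1 + p) / (1 - p)                    # bilinear transform, T = 2
  z_zero <- if (type == "low") -1 else 1     # zeros map from s = Inf / s = 0

  # Pair conjugate poles; a lone real pole (odd order) gets a 1st-order section.
  is_real <- abs(Im(zd)) < 1e-12
  cplx <- zd[!is_real & Im(zd) > 0]
  real_p <- Re(zd[is_real])
  sec <- list()
  for (pp in cplx) {
    a <- c(1, -2 * Re(pp), Mod(pp)^2)
    b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    sec[[length(sec) + 1L]] <- c(b, a)
  }
  for (rp in real_p) {
    a <- c(1, -rp, 0)
    b <- if (type == "low") c(1, 1, 0) else c(1, -1, 0)
    sec[[length(sec) + 1L]] <- c(b, a)
  }
  sos <- do.call(rbind, sec)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  # Normalize passband gain to 1 at DC (low pass) or Nyquist (high pass).
  z0 <- if (type == "low") 1 + 0i else -1 + 0i
  h <- prod(apply(sos, 1L, function(s) {
    (s[1] + s[2] / z0 + s[3] / z0^2) / (s[4] + s[5] / z0 + s[6] / z0^2)
  }))
  sos[1L, 1:3] <- sos[1L, 1:3] / abs(h)
  sos
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos Section matrix from [butter_sos()].
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Complex response at `f`.
#' @keywords internal
sos_freqz <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h <- h * (b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2)
  }
  h
}

# Time-reversal-symmetric zero-phase filtering: odd-reflection padding
# sized by the slowest pole's decay (suppresses end transients), then the
# average of the forward-then-backward and backward-then-forward passes,
# which commutes exactly with time reversal. Core runs in C++.
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  rmax <- max(vapply(seq_len(nrow(sos)), function(s) {
    max(Mod(polyroot(rev(sos[s, 4:6]))), 0)
  }, 0))
  pad <- if (rmax < 1) min(n - 1L, ceiling(6 / (1 - rmax))) else n - 1L
  sosfiltfilt_cpp(as.numeric(x), sos, as.integer(pad))
}

#' Zero-phase filtering of one trace
#'
#' Applies the high-pass and/or low-pass stages of a [filter_spec()] as
#' Butterworth second-order sections run forward and backward, so the output
#' has no group delay and CSD onset times are not biased by the filter.
#'
#' @param trace Numeric vector of potential samples (mV).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered trace, same length as the input.
#' @examples
#' fs <- 300
#' x <- 5 + sin(2 * pi * 2 * seq(0, 10, by = 1 / fs))
#' y <- apply_filter(x, fs, epi_filter_spec())
#' abs(mean(y)) < 0.01  # DC offset removed
#' @export
apply_filter <- function(trace, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(trace), fs > 0)
  nyq <- fs / 2
  for (cut in c(spec$highpass_hz, spec$lowpass_hz)) {
    if (!is.null(cut) && (cut <= 0 || cut >= nyq)) {
      stop("filter cutoff ", cut, " Hz outside (0, ", nyq, ") for fs = ", fs)
    }
  }
  sos <- NULL
  if (!is.null(spec$highpass_hz)) {
    sos <- butter_sos(spec$order, spec$highpass_hz / nyq, "high")
  }
  if (!is.null(spec$lowpass_hz)) {
    sos <- rbind(sos, butter_sos(spec$order, spec$lowpass_hz / nyq, "low"))
  }
  if (is.null(sos)) return(as.numeric(trace))
  sos_filtfilt(as.numeric(trace), sos)
}

#' Anti-aliased downsampling of a recording
#'
#' Low-pass filters each channel (zero-phase 8th-order Butterworth at 0.4 of
#' the target rate) and resamples by linear interpolation onto the new sample
#' grid, preserving the recording duration to within one sample.
#'
#' @param rec An [ecog_recording()].
#' @param target_hz Target sampling rate; must not exceed `rec$fs`.
#' @return A new recording at `target_hz`.
#' @export
downsample <- function(rec, target_hz) {
  stopifnot(inherits(rec, "ecog_recording"), target_hz > 0)
  if (target_hz > rec$fs) stop("target_hz exceeds the recording sampling rate")
  if (isTRUE(all.equal(target_hz, rec$fs))) return(rec)
  n <- nrow(rec$data)
  n_new <- round(n * target_hz / rec$fs)
  t_old <- (seq_len(n) - 1) / rec$fs
  t_new <- (seq_len(n_new) - 1) / target_hz
  sos <- butter_sos(8L, (0.4 * target_hz) / (rec$fs / 2), "low")
  out <- vapply(seq_len(ncol(rec$data)), function(j) {
    y <- sos_filtfilt(rec$data[, j], sos)
    stats::approx(t_old, y, xout = t_new, rule = 2)$y
  }, numeric(n_new))
  colnames(out) <- colnames(rec$data)
  rec$data <- out
  rec$fs <- target_hz
  rec
}
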