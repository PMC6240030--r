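# Normalized cross-correlation between epileptiform-band traces. The
# "coeff" normalization scales the correlogram so the zero-lag
# autocorrelation of any trace is 1, bounding coefficients in [-1, 1].
# Traces are demeaned first, which makes the coefficient invariant under
# per-channel gain and offset (the inputs are high-pass filtered, so the
# mean is ~0 anyway). Lag sign convention: positive lag means the
# first-named channel leads.

#' Normalized cross-correlogram of two traces
#'
#' Computes `r(l) = sum_t x[t] y[t + l]` for signed lags up to `max_lag_s`,
#' normalized by the zero-lag autocorrelations, via FFT. A positive peak
#' lag means `x` leads `y`.
#'
#' @param x,y Equal-length traces (mV).
#' @param fs Sampling rate, Hz.
#' @param max_lag_s Maximum |lag| evaluated, seconds.
#' @return List of class `correlogram`: `lag_s` (signed lag grid at 1/fs
#'   resolution) and `coeff`.
#' @export
xcorr_coeff <- function(x, y, fs, max_lag_s = 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("traces must have equal length")
  n <- length(x)
  L <- round(max_lag_s * fs)
  if (L >= n) stop("max_lag_s must be shorter than the traces")
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) {
    stop("undefined-correlation error: zero-variance input")
  }
  nfft <- n + L
  xp <- c(x, numeric(nfft - n))
  yp <- c(y, numeric(nfft - n))
  r <- Re(fft(Conj(fft(xp)) * fft(yp), inverse = TRUE)) / nfft
  # r[1 + l] holds lag l for l >= 0; negative lags wrap to the end
  coeff <- c(r[(nfft - L + 1L):nfft], r[1:(L + 1L)]) / (sx * sy)
  structure(list(lag_s = (-L:L) / fs, coeff = coeff, fs = fs),
            class = "correlogram")
}

#' Peak of a correlogram
#'
#' Global maximum coefficient and its lag. Ties are broken toward the lag
#' of smallest absolute value; an exact +/- tie resolves to the negative
#' lag.
#'
#' @param cg A [xcorr_coeff()] result.
#' @return List with `max_coeff` and `lag_s`.
#' @export
max_xcorr <- function(cg) {
  stopifnot(inherits(cg, "correlogram"), length(cg$coeff) > 0)
  m <- max(cg$coeff)
  tol <- 1e-12 * max(1, abs(m))
  cand <- which(cg$coeff >= m - tol)
  lags <- cg$lag_s[cand]
  cand <- cand[abs(lags) == min(abs(lags))]
  lags <- cg$lag_s[cand]
  pick <- cand[which.min(lags)]       # negative lag on a +/- tie
  list(max_coeff = cg$coeff[pick], lag_s = cg$lag_s[pick])
}

# Internal: pairwise results from pre-filtered per-channel traces.
pairwise_xcorr_traces <- function(traces, fs, max_lag_s = 2,
                                  keep_correlograms = FALSE) {
  pairs <- list(c("M1_left", "S1_left"),
                c("M1_left", "M1_right"),
                c("S1_left", "M1_right"))
  for (role in unique(unlist(pairs))) {
    if (stats::sd(traces[[role]]) < 1e-12) {
      stop("channel QC error: channel ", role,
           " is flat in the analysis window; subject must be excluded")
    }
  }
  rows <- lapply(pairs, function(p) {
    cg <- xcorr_coeff(traces[[p[1]]], traces[[p[2]]], fs, max_lag_s)
    mx <- max_xcorr(cg)
    list(row = data.frame(ch1 = p[1], ch2 = p[2],
                          max_coeff = mx$max_coeff, lag_s = mx$lag_s),
         cg = cg)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (keep_correlograms) {
    attr(out, "correlograms") <- lapply(rows, `[[`, "cg")
  }
  class(out) <- c("xcorr_results", "data.frame")
  out
}

#' Pairwise cross-correlation of the three ECoG channels
#'
#' Filters each channel with the epileptiform chain over the analysis
#' window (the terminal 10 minutes by default, where activity is
#' strongest) and computes the normalized cross-correlogram peak for the
#' three channel combinations (M1_left vs S1_left, M1_left vs M1_right,
#' S1_left vs M1_right). A flat channel raises a QC error mirroring the
#' study's exclusion of subjects with a bad electrode.
#'
#' @param rec An [ecog_recording()].
#' @param window `"last600"`, `"full"`, or a numeric `c(start, stop)` in
#'   seconds.
#' @param max_lag_s Maximum |lag| evaluated, seconds.
#' @param filter A [filter_spec()] for the epileptiform chain.
#' @param keep_correlograms Attach full correlograms as an attribute.
#' @return `data.frame` of class `xcorr_results` with columns `ch1`,
#'   `ch2`, `max_coeff`, `lag_s` (positive lag = `ch1` leads).
#' @export
pairwise_xcorr <- function(rec, window = "last600", max_lag_s = 2,
                           filter = epi_filter_spec(),
                           keep_correlograms = FALSE) {
  stopifnot(inherits(rec, "ecog_recording"))
  dur <- recording_duration(rec)
  if (identical(window, "last600")) {
    window <- c(max(dur - 600, 0), dur)
  } else if (identical(window, "full")) {
    window <- c(0, dur)
  }
  stopifnot(is.numeric(window), length(window) == 2L, window[2] > window[1])
  i0 <- max(1L, floor(window[1] * rec$fs) + 1L)
  i1 <- min(nrow(rec$data), floor(window[2] * rec$fs))
  traces <- lapply(rec$channels, function(role) {
    seg <- rec$data[i0:i1, role]
    if (stats::sd(seg) < 1e-12) return(seg)   # leave flat for the QC check
    apply_filter(seg, rec$fs, adapt_spec(filter, rec$fs))
  })
  names(traces) <- rec$channels
  pairwise_xcorr_traces(traces, rec$fs, max_lag_s, keep_correlograms)
}
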