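# Small fixtures shared across tests. Everything is generated in code.

# A short 3-channel recording with analytic content: slow sine + per-channel
# offsets, cheap to filter and to round-trip through files.
tiny_recording <- function(fs = 100, dur = 3, seed = 42) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  dat <- cbind(sin(2 * pi * 1 * t) + 0.1 * rnorm(length(t)),
               cos(2 * pi * 2 * t) + 0.1 * rnorm(length(t)),
               0.5 * sin(2 * pi * 3 * t) + 0.1 * rnorm(length(t)))
  ecog_recording(dat, fs = fs,
                 subject = subject_meta("G301R", "female", "t1"))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments;
# independent of the implementation under test.
enum_mw <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- c(a, b)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(u1 = u_obs, u2 = n1 * n2 - u_obs,
       p = min(1, 2 * min(p_le, p_ge)))
}

# Welch-free band RMS used as an independent check of filter attenuation.
rms <- function(x) sqrt(mean(x^2))
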