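#' @useDynLib csdscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx mad median rnorm runif rexp rgamma rlnorm fft
#'   kruskal.test wilcox.test t.test lm pnorm pt coef sd quantile
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

# Channel roles, in the conventional order. CSDs are induced by KCl on the
# left occipital cortex, so M1_left and S1_left are ipsilateral to the
# induction site and M1_right is the contralateral control.
CHANNEL_ROLES <- c("M1_left", "S1_left", "M1_right")

# Distance between the two ipsilateral electrodes (M1 left and S1 left), mm.
ELECTRODE_DISTANCE_MM <- 2

#' Subject metadata
#'
#' @param genotype `"WT"` or `"G301R"` (heterozygous alpha2 Na+/K+-ATPase
#'   G301R, the FHM2 disease mutation).
#' @param group Experimental group: `"male"`, `"female"`, `"aged_male"` or
#'   `"PM_female"` (post-menopausal female).
#' @param subject_id Free-form identifier.
#' @return Object of class `subject_meta`.
#' @export
subject_meta <- function(genotype = c("WT", "G301R"),
                         group = c("male", "female", "aged_male", "PM_female"),
                         subject_id = "s1") {
  genotype <- match.arg(genotype)
  group <- match.arg(group)
  structure(list(genotype = genotype, group = group,
                 subject_id = as.character(subject_id)),
            class = "subject_meta")
}

#' Multi-channel DC-coupled ECoG recording
#'
#' The central data container: a samples-by-channels matrix of potentials in
#' millivolts, its sampling rate, the channel roles, the time origin (0 =
#' start of the KCl application / recording) and subject metadata.
#'
#' @param data Numeric matrix (rows = samples, columns = channels) or a list
#'   of equal-length numeric vectors. Values in mV.
#' @param fs Sampling rate in Hz.
#' @param channels Channel roles, one per column; must be unique and drawn
#'   from `M1_left`, `S1_left`, `M1_right`.
#' @param t0 Time of the first sample in seconds.
#' @param subject A [subject_meta()].
#' @return Object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, fs, channels = CHANNEL_ROLES, t0 = 0,
                           subject = subject_meta()) {
  if (is.list(data) && !is.data.frame(data)) {
    lens <- lengths(data)
    if (length(unique(lens)) != 1L) stop("channels have mismatched lengths")
    data <- do.call(cbind, data)
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  channels <- as.character(channels)
  if (length(channels) != ncol(data)) {
    stop("need one channel role per data column")
  }
  if (anyDuplicated(channels)) stop("channel roles must be unique")
  if (!all(channels %in% CHANNEL_ROLES)) {
    stop("unknown channel role(s): ",
         paste(setdiff(channels, CHANNEL_ROLES), collapse = ", "))
  }
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, t0 = t0,
                 subject = subject),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, recording_duration(x)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  subject: %s [%s, %s], t0 = %g s\n", x$subject$subject_id,
              x$subject$genotype, x$subject$group, x$t0))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [ecog_recording()].
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$fs

#' Extract one channel by role
#' @param rec An [ecog_recording()].
#' @param role One of `M1_left`, `S1_left`, `M1_right`.
#' @return Numeric vector of samples (mV).
#' @export
get_channel <- function(rec, role) {
  if (!role %in% rec$channels) stop("recording has no channel with role ", role)
  rec$data[, role]
}
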