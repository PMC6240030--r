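# File formats:
#  - delimited: CSV with one header row of channel labels plus a key-value
#    sidecar (<path>.meta) holding fs, t0, subject fields and the
#    label -> role map. Human-readable interchange.
#  - container: RDS serialization of the ecog_recording. Lossless native.
#  - edf: standard 16-bit European Data Format, for interchange with
#    clinical/electrophysiology viewers. Lossy to 16-bit quantization.

# Labels commonly seen in acquisition software, mapped to roles.
ROLE_ALIASES <- c(
  "M1_left" = "M1_left", "M1L" = "M1_left", "M1-L" = "M1_left",
  "M1 LEFT" = "M1_left", "M1_LEFT" = "M1_left",
  "S1_left" = "S1_left", "S1L" = "S1_left", "S1-L" = "S1_left",
  "S1 LEFT" = "S1_left", "S1_LEFT" = "S1_left",
  "M1_right" = "M1_right", "M1R" = "M1_right", "M1-R" = "M1_right",
  "M1 RIGHT" = "M1_right", "M1_RIGHT" = "M1_right")

resolve_roles <- function(labels, roles_hint = NULL) {
  if (!is.null(roles_hint)) {
    if (length(roles_hint) != length(labels)) {
      stop("role-mapping error: sidecar lists ", length(roles_hint),
           " roles for ", length(labels), " channels")
    }
    return(as.character(roles_hint))
  }
  key <- toupper(trimws(labels))
  hit <- ROLE_ALIASES[match(key, toupper(names(ROLE_ALIASES)))]
  if (anyNA(hit)) {
    stop("role-mapping error: cannot resolve channel label(s) ",
         paste(labels[is.na(hit)], collapse = ", "),
         " to roles and no sidecar role map was given")
  }
  unname(hit)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = , tsv = , txt = "delimited",
         rds = "container",
         edf = "edf",
         stop("cannot guess format from extension '", ext, "'"))
}

#' Read a recording from disk
#'
#' @param path Input file. The format is guessed from the extension
#'   (`.csv`/`.tsv` delimited, `.rds` container, `.edf` EDF) unless given.
#' @param format `"delimited"`, `"container"` or `"edf"`.
#' @return An [ecog_recording()].
#' @seealso [write_recording()]
#' @export
load_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (is.null(format)) guess_format(path) else
    match.arg(format, c("delimited", "container", "edf"))
  switch(format,
         delimited = read_delimited(path),
         container = read_container(path),
         edf = read_edf(path))
}

#' Write a recording to disk
#'
#' @param rec An [ecog_recording()].
#' @param path Output file.
#' @param format See [load_recording()]; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  format <- if (is.null(format)) guess_format(path) else
    match.arg(format, c("delimited", "container", "edf"))
  switch(format,
         delimited = write_delimited(rec, path),
         container = saveRDS(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta")

write_delimited <- function(rec, path) {
  df <- as.data.frame(rec$data)
  names(df) <- rec$channels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(
    sprintf("fs: %.10g", rec$fs),
    sprintf("t0: %.10g", rec$t0),
    sprintf("subject_id: %s", rec$subject$subject_id),
    sprintf("genotype: %s", rec$subject$genotype),
    sprintf("group: %s", rec$subject$group),
    sprintf("channel_roles: %s", paste(rec$channels, collapse = ",")))
  writeLines(meta, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) trimws(m[2]), "")
  vals <- vapply(kv, function(m) trimws(m[3]), "")
  stats::setNames(as.list(vals), keys)
}

read_delimited <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L) stop("format error: no channels in ", path)
  meta <- read_sidecar(path)
  if (is.null(meta) || is.null(meta$fs)) {
    stop("format error: delimited recording needs a sidecar ",
         sidecar_path(path), " with at least 'fs'")
  }
  roles_hint <- if (!is.null(meta$channel_roles)) {
    trimws(strsplit(meta$channel_roles, ",")[[1]])
  }
  roles <- resolve_roles(names(df), roles_hint)
  subj <- subject_meta(
    genotype = if (!is.null(meta$genotype)) meta$genotype else "WT",
    group = if (!is.null(meta$group)) meta$group else "male",
    subject_id = if (!is.null(meta$subject_id)) meta$subject_id else "s1")
  ecog_recording(as.matrix(df), fs = as.numeric(meta$fs),
                 channels = roles,
                 t0 = if (!is.null(meta$t0)) as.numeric(meta$t0) else 0,
                 subject = subj)
}

read_container <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "ecog_recording")) {
    stop("format error: ", path, " does not hold an ecog_recording")
  }
  rec
}

# --- EDF (European Data Format), 16-bit standard variant ------------------
# 256-byte fixed header + 256 bytes per signal, then data records of
# `fs * record_s` two-byte little-endian integers per signal. One-second
# records; the last partial second is zero-padded on write and trimmed on
# read using the sample count stored in the reserved header field.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- ncol(rec$data)
  n <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(n / fs))
  pmin_ <- apply(rec$data, 2, min)
  pmax_ <- apply(rec$data, 2, max)
  span <- pmax_ - pmin_
  pmin_ <- pmin_ - ifelse(span == 0, 1, 0.001 * span)
  pmax_ <- pmax_ + ifelse(span == 0, 1, 0.001 * span)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(paste(rec$subject$subject_id, rec$subject$genotype,
                  rec$subject$group), 80L),
    edf_pad("csdscope ECoG", 80L),
    edf_pad("01.01.20", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L),
    edf_pad(sprintf("n=%d t0=%.6g", n, rec$t0), 44L),
    edf_pad(n_rec, 8L),
    edf_pad("1", 8L),
    edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channels, 16L)                       # labels
  field(rep("AgAgCl cortical", ns), 80L)         # transducer
  field(rep("mV", ns), 8L)                       # physical dimension
  field(sprintf("%.8g", pmin_), 8L)
  field(sprintf("%.8g", pmax_), 8L)
  field(rep(dmin, ns), 8L)
  field(rep(dmax, ns), 8L)
  field(rep("HP:0.001Hz LP:1kHz", ns), 80L)      # prefiltering
  field(rep(fs, ns), 8L)                         # samples per record
  field(rep("", ns), 32L)                        # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  pad <- n_rec * fs - n
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * fs
    for (j in seq_len(ns)) {
      idx <- i0 + seq_len(fs)
      x <- rec$data[idx[idx <= n], j]
      if (length(x) < fs) x <- c(x, rep(0, fs - length(x)))
      dig <- as.integer(round((x - pmin_[j]) / scale[j]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                       # version
  patient <- rd(80L)
  rd(80L); rd(8L); rd(8L)
  rd(8L)                       # header bytes
  reserved <- rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16L)
  rdv(80L); rdv(8L)
  pmin_ <- as.numeric(rdv(8L))
  pmax_ <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L))
  dmax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  if (length(unique(spr)) != 1L) {
    stop("format error: channels with different sampling rates")
  }
  fs <- spr[1L] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1L], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2L,
                     signed = TRUE, endian = "little")
      out[(r - 1L) * spr[j] + seq_len(spr[j]), j] <- dig
    }
  }
  for (j in seq_len(ns)) {
    out[, j] <- pmin_[j] + (out[, j] - dmin[j]) *
      (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
  }
  m <- regmatches(reserved, regexec("n=(\\d+) t0=([-0-9.eE+]+)", reserved))[[1]]
  t0 <- 0
  if (length(m) == 3L) {
    out <- out[seq_len(as.integer(m[2])), , drop = FALSE]
    t0 <- as.numeric(m[3])
  }
  subj <- subject_meta()
  pf <- strsplit(patient, " +")[[1]]
  if (length(pf) >= 3L && pf[2] %in% c("WT", "G301R") &&
      pf[3] %in% c("male", "female", "aged_male", "PM_female")) {
    subj <- subject_meta(pf[2], pf[3], pf[1])
  }
  ecog_recording(out, fs = fs, channels = resolve_roles(labels),
                 t0 = t0, subject = subj)
}
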