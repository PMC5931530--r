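# Minimal EDF (European Data Format) I/O, sufficient for round-tripping
# multichannel EEG fixtures: fixed-width ASCII headers and little-endian
# 16-bit data records, one sampling rate across channels.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop("EDF field too long (", width, "): ", s)
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Emits a standard-conformant EDF file (one data record per second when
#' the duration is a whole number of seconds, otherwise a single record).
#' Samples are quantized to the 16-bit digital range against a symmetric
#' physical range per channel, so a round trip through [read_edf()]
#' reproduces the data within one quantization step.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  whole_seconds <- n %% rec$fs == 0 && rec$fs == round(rec$fs)
  if (whole_seconds) {
    n_rec <- n %/% rec$fs
    spr <- as.integer(rec$fs)
    rec_dur <- 1
  } else {
    n_rec <- 1L
    spr <- n
    rec_dur <- n / rec$fs
  }

  pm <- apply(abs(rec$samples), 1L, max)
  pm[pm == 0] <- 1
  # quantize against the header-precision physical range so the ASCII
  # round trip is exact
  pmax_s <- vapply(pm, function(v) .edf_num(v, 8), character(1))
  pmin_s <- vapply(pm, function(v) .edf_num(-v, 8), character(1))
  pmax_v <- as.numeric(pmax_s)
  pmin_v <- as.numeric(pmin_s)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80))
  wr(.edf_pad("eegdyn fixture", 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256 * (ns + 1), 8))
  wr(.edf_pad("", 44))
  wr(.edf_pad(n_rec, 8))
  wr(.edf_num(rec_dur, 8))
  wr(.edf_pad(ns, 4))
  for (lab in rec$channel_labels) wr(.edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(pmin_s[i])
  for (i in seq_len(ns)) wr(pmax_s[i])
  for (i in seq_len(ns)) wr(.edf_pad(-32768, 8))
  for (i in seq_len(ns)) wr(.edf_pad(32767, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(spr, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  gain <- (pmax_v - pmin_v) / 65535
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      d <- round((rec$samples[i, cols] - pmin_v[i]) / gain[i]) - 32768
      d <- pmin(pmax(d, -32768), 32767)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the fixed-width header and 16-bit data records and returns the
#' samples in physical units. All signals must share one sampling rate
#' (mixed per-channel rates are rejected); a file shorter than its declared
#' record count raises an error naming the first incomplete record.
#'
#' @param path path to an EDF/EDF+ file.
#' @return An `eeg_recording` with labels, sampling rate and subject id
#'   taken from the header.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nch) readChar(con, nch, useBytes = TRUE)
  num <- function(nch) {
    s <- trimws(rd(nch))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("malformed EDF header field: '", s, "'")
    v
  }
  version <- trimws(rd(8))
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  header_bytes <- num(8)
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  if (ns < 1) stop("malformed EDF header: no signals")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported (",
         paste(unique(spr), collapse = ", "), " samples/record)")
  sp <- spr[1]
  if (header_bytes != 256 * (ns + 1))
    stop("malformed EDF header: inconsistent header byte count")

  gain <- (pmax - pmin) / (dmax - dmin)
  samples <- matrix(NA_real_, ns, n_rec * sp)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * sp, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(raw) < ns * sp)
      stop("truncated EDF file at data record ", r, " of ", n_rec)
    block <- matrix(raw, nrow = sp)          # column per signal
    cols <- ((r - 1L) * sp + 1L):(r * sp)
    samples[, cols] <- t(block * rep(gain, each = sp) +
                           rep(pmin - gain * dmin, each = sp))
  }
  fs <- sp / rec_dur
  eeg_recording(samples, labels, fs,
                subject_id = if (nzchar(patient)) patient else NA_character_)
}

#' Write a synthetic fixture EDF
#'
#' Thin wrapper over [write_edf()] kept as the named entry point for
#' producing test fixtures from generated recordings.
#'
#' @inheritParams write_edf
#' @return `path`, invisibly.
#' @export
write_fixture_edf <- function(rec, path) write_edf(rec, path)
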