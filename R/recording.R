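#' @useDynLib eegdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 19-channel 10-20 montage
#'
#' Ordered electrode labels of the standard 10-20 scalp montage used for
#' all feature indexing. The order is fixed: feature vectors, difference
#' maps and region presets all refer to channels in this order.
#'
#' @return Character vector of 19 electrode labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
    "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param channel_labels character vector, one unique label per row.
#' @param fs sampling rate in Hz.
#' @param subject_id opaque subject identifier.
#' @param age_months visit age in months (optional).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, channel_labels, fs,
                          subject_id = NA_character_, age_months = NA_real_) {
  samples <- as.matrix(samples)
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length must equal number of sample rows")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = subject_id, channel_labels = as.character(channel_labels),
         fs = fs, samples = samples, age_months = age_months),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Select and order the 10-20 montage channels
#'
#' Keeps exactly the 19 montage channels, in canonical order, dropping all
#' others. Labels are matched directly or through an alias map (named
#' character vector mapping recording labels to montage labels), which is
#' how high-density net channels are resolved; no positional guessing is
#' performed.
#'
#' @param rec an `eeg_recording`.
#' @param montage ordered montage labels; default [montage_1020()].
#' @param alias optional named character vector: `names(alias)` are labels
#'   present in the recording, values are the montage labels they stand for.
#' @return An `eeg_recording` with exactly the montage channels, in order.
#' @export
select_montage <- function(rec, montage = montage_1020(), alias = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- rec$channel_labels
  resolved <- labels
  if (!is.null(alias)) {
    hit <- labels %in% names(alias)
    resolved[hit] <- unname(alias[labels[hit]])
  }
  idx <- match(montage, resolved)
  if (anyNA(idx)) {
    stop("montage channels missing from recording: ",
         paste(montage[is.na(idx)], collapse = ", "))
  }
  eeg_recording(rec$samples[idx, , drop = FALSE], montage, rec$fs,
                subject_id = rec$subject_id, age_months = rec$age_months)
}

#' Normalize the sampling rate to 250 Hz
#'
#' 500 Hz recordings are low-pass filtered (8th-order Butterworth at 100 Hz,
#' i.e. 0.8 x the target Nyquist, applied forward-backward so the passband
#' has zero phase shift) and decimated by two. 250 Hz input is returned
#' unchanged.
#'
#' @param rec an `eeg_recording` sampled at 250 or 500 Hz.
#' @return An `eeg_recording` at 250 Hz of identical duration in seconds.
#' @export
resample_to_250 <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == 250) return(rec)
  if (rec$fs != 500)
    stop("unsupported sampling rate ", rec$fs, " Hz (expected 250 or 500)")
  bf <- signal::butter(8, 0.8 * 125 / 250)  # normalized to input Nyquist 250
  filtered <- t(apply(rec$samples, 1L, function(x)
    signal::filtfilt(bf, x)))
  keep <- seq(1L, ncol(filtered), by = 2L)
  eeg_recording(filtered[, keep, drop = FALSE], rec$channel_labels, 250,
                subject_id = rec$subject_id, age_months = rec$age_months)
}

#' Extract the leading analysis segment
#'
#' Takes the first `duration_s` seconds of every channel, from `offset_s`.
#' No splicing or data-driven segment selection is performed.
#'
#' @param rec an `eeg_recording`.
#' @param duration_s segment length in seconds.
#' @param offset_s start offset in seconds (default 0).
#' @return An `eeg_recording` of exactly `duration_s` seconds.
#' @export
extract_segment <- function(rec, duration_s, offset_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"), duration_s > 0, offset_s >= 0)
  n_need <- as.integer(round((offset_s + duration_s) * rec$fs))
  if (ncol(rec$samples) < n_need)
    stop(sprintf("recording too short: %d samples available, %d required",
                 ncol(rec$samples), n_need))
  i0 <- as.integer(round(offset_s * rec$fs))
  idx <- (i0 + 1L):n_need
  eeg_recording(rec$samples[, idx, drop = FALSE], rec$channel_labels, rec$fs,
                subject_id = rec$subject_id, age_months = rec$age_months)
}

# run f with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so package functions never perturb the global RNG
with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  f()
}
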