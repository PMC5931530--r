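#' Canonical feature names
#'
#' The 19 x 6 x 9 = 1026 feature names, sensor-major in montage order,
#' then band (level 1, highest frequencies, to level 6), then measure in
#' the canonical order. Names have the form `"<sensor>.<band>.<measure>"`
#' (e.g. `"Fp1.high_gamma.RR"`) and are stable across runs and versions:
#' they define feature indexing everywhere downstream.
#'
#' @param montage ordered sensor labels; default [montage_1020()].
#' @return Character vector of `19 * 6 * 9` names.
#' @export
feature_names <- function(montage = montage_1020()) {
  bands <- .band_labels
  measures <- nld_measure_names()
  as.vector(vapply(montage, function(s)
    vapply(bands, function(b) paste(s, b, measures, sep = "."),
           character(length(measures))),
    character(length(bands) * length(measures))))
}

#' Extract the nonlinear feature vector of one session
#'
#' Decomposes every channel into the six dyadic wavelet bands and computes
#' the nine nonlinear measures per band, yielding the named 1026-element
#' feature vector. Degenerate cells (NaN sentinels from constituent
#' measures) are recorded in the sentinel mask and imputed later, inside
#' classification folds.
#'
#' @param rec an `eeg_recording` with exactly the 19 montage channels, at
#'   250 Hz. The expected duration is checked when `expect_duration_s` is
#'   non-NULL (default 30 s, the standard analysis segment).
#' @param settings an [nld_settings()] list.
#' @param expect_duration_s expected segment length in seconds, or NULL to
#'   accept any length.
#' @return Named numeric vector of length 1026 with attributes
#'   `sentinel_mask` (logical), `subject_id`, `age_months` and `settings`.
#' @export
extract_features <- function(rec, settings = nld_settings(),
                             expect_duration_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  montage <- montage_1020()
  if (!identical(rec$channel_labels, montage))
    stop("recording must contain exactly the 19 montage channels in ",
         "canonical order (run select_montage first)")
  if (rec$fs != 250) stop("recording must be sampled at 250 Hz")
  if (!is.null(expect_duration_s)) {
    dur <- ncol(rec$samples) / rec$fs
    if (abs(dur - expect_duration_s) > 1e-9)
      stop(sprintf("expected a %g s segment, got %g s",
                   expect_duration_s, dur))
  }
  nm <- feature_names(montage)
  values <- numeric(length(nm))
  k <- 0L
  for (ci in seq_along(montage)) {
    bs <- wavelet_bands(rec$samples[ci, ], rec$fs)
    for (bi in 1:6) {
      mv <- channel_band_measures(bs$bands[[bi]], settings)
      values[k + 1:9] <- as.numeric(mv)
      k <- k + 9L
    }
  }
  names(values) <- nm
  attr(values, "sentinel_mask") <- !is.finite(values)
  attr(values, "subject_id") <- rec$subject_id
  attr(values, "age_months") <- rec$age_months
  attr(values, "settings") <- settings
  values
}

#' Combine feature vectors from two visit ages
#'
#' Concatenates the two sessions' vectors into a single 2052-element
#' vector with age-prefixed names (`"m6.Fp1.high_gamma.RR"`, ...), the
#' representation used when measurements from two visits are pooled for
#' one classification.
#'
#' @param v1,v2 feature vectors from [extract_features()] for the same
#'   subject at two different ages.
#' @return Named numeric vector of length `length(v1) + length(v2)`.
#' @export
combine_ages <- function(v1, v2) {
  s1 <- attr(v1, "subject_id"); s2 <- attr(v2, "subject_id")
  a1 <- attr(v1, "age_months"); a2 <- attr(v2, "age_months")
  if (!identical(s1, s2))
    stop("cannot combine visits from different subjects (", s1, ", ", s2, ")")
  if (isTRUE(a1 == a2)) stop("visits must come from different ages")
  pre <- function(v, a) {
    out <- as.numeric(v)
    names(out) <- paste0("m", a, ".", names(v))
    out
  }
  out <- c(pre(v1, a1), pre(v2, a2))
  attr(out, "sentinel_mask") <- !is.finite(out)
  attr(out, "subject_id") <- s1
  attr(out, "age_months") <- c(a1, a2)
  out
}

#' Feature matrix for a cohort
#'
#' Convenience driver: featurizes a list of recordings and binds the
#' vectors into a sessions x features matrix aligned with an outcomes
#' table.
#'
#' @param recordings list of `eeg_recording`s (montage-selected, 250 Hz).
#' @param settings an [nld_settings()] list.
#' @param expect_duration_s passed to [extract_features()].
#' @return Numeric matrix with rownames `<subject_id>@<age>` and the 1026
#'   feature columns.
#' @export
cohort_features <- function(recordings, settings = nld_settings(),
                            expect_duration_s = NULL) {
  rows <- lapply(recordings, extract_features, settings = settings,
                 expect_duration_s = expect_duration_s)
  mat <- do.call(rbind, lapply(rows, as.numeric))
  colnames(mat) <- names(rows[[1]])
  rownames(mat) <- vapply(recordings, function(r)
    paste0(r$subject_id, "@", r$age_months), character(1))
  mat
}

#' Write / read a feature table as CSV
#'
#' Serializes a feature matrix together with the outcome columns
#' (`subject_id`, `group`, `css`, `age_months`) at full precision.
#'
#' @param features sessions x features numeric matrix.
#' @param outcomes data.frame aligned row-for-row with `features`.
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table` returns a list
#'   `(features, outcomes)`.
#' @export
write_feature_table <- function(features, outcomes, path) {
  stopifnot(nrow(features) == nrow(outcomes))
  df <- cbind(outcomes, as.data.frame(features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("subject_id", "group", "css", "age_months"),
                         names(df))
  feats <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  list(features = feats, outcomes = df[, meta_cols, drop = FALSE])
}
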