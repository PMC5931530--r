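#' Simulate fractional Gaussian noise
#'
#' Exact simulation by Davies-Harte circulant embedding: the fGn
#' autocovariance is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT, and a Gaussian vector with that spectrum is synthesized.
#' For fGn the embedding is nonnegative-definite, so the draw has exactly
#' the target covariance (unit variance, Hurst parameter `H`).
#'
#' @param n number of samples.
#' @param H Hurst parameter in (0, 1). `H = 0.5` is white noise; larger
#'   values give persistent long-range correlation.
#' @return Numeric vector of length `n`.
#' @export
fgn_sim <- function(n, H) {
  stopifnot(n >= 1, H > 0, H < 1)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  m <- 2L * n
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row <- if (n > 1) c(g, rev(g[2:n])) else g
  lam <- pmax(Re(stats::fft(row)), 0)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1]) * stats::rnorm(1)
  w[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  if (n > 1) {
    j <- 2:n
    w[j] <- sqrt(lam[j] / 2) *
      complex(real = stats::rnorm(n - 1), imaginary = stats::rnorm(n - 1))
    w[m - j + 2] <- Conj(w[j])
  }
  Re(stats::fft(w))[1:n] / sqrt(m)
}

#' Default sensor/band cells carrying the synthetic group effect
#'
#' Temporal/parietal sensors in the beta and gamma bands plus occipital
#' sensors in delta: the regions where infant-EEG group contrasts in sample
#' entropy and determinism are most consistently reported.
#'
#' @return data.frame with columns `sensor` and `band`.
#' @export
default_effect_cells <- function() {
  rbind(
    expand.grid(sensor = c("T7", "T8", "P4", "P8"),
                band = c("beta", "gamma"),
                stringsAsFactors = FALSE),
    data.frame(sensor = c("O1", "O2"), band = "delta",
               stringsAsFactors = FALSE))
}

#' Specify a synthetic cohort
#'
#' Bundles the design of a simulated study: group sizes, visit ages,
#' recording geometry, and the dimensionless effect size separating the
#' latent group dynamics. With `effect_size = 0` group and severity have no
#' influence on the signals (an exact null).
#'
#' @param n_per_group subjects per outcome group.
#' @param groups outcome groups, subset of `"LRC-"`, `"HRA-"`, `"ASD"`.
#' @param ages_months visit ages; one recording per subject per age.
#' @param n_channels channels per recording (default 19, the 10-20 montage).
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param effect_size separation of group dynamics (0 = null; ~2 = strong).
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @param effect_cells data.frame(sensor, band) of cells carrying the
#'   group/severity effect; default [default_effect_cells()].
#' @param hurst_shift per-unit-effect-size increase of the Hurst parameter
#'   of effect-channel noise with the latent group (default 0.15). Set to 0
#'   to confine the group effect strictly to the listed cells (the noise
#'   shift colors a whole channel's spectrum).
#' @param age_flip if TRUE, the sign of the group contrast flips for visits
#'   at 12 months or later (a developmental crossover); off by default.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = c("LRC-", "HRA-", "ASD"),
                        ages_months = 6,
                        n_channels = 19, fs = 250, duration_s = 30,
                        effect_size = 1, seed = 1,
                        effect_cells = default_effect_cells(),
                        hurst_shift = 0.15, age_flip = FALSE) {
  if (length(groups) < 1) stop("at least one outcome group required")
  groups <- match.arg(groups, c("LRC-", "HRA-", "ASD"), several.ok = TRUE)
  stopifnot(n_per_group >= 1, fs > 0, duration_s > 0, n_channels >= 1)
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         ages_months = ages_months, n_channels = as.integer(n_channels),
         fs = fs, duration_s = duration_s, effect_size = effect_size,
         seed = as.integer(seed), effect_cells = effect_cells,
         hurst_shift = hurst_shift, age_flip = isTRUE(age_flip)),
    class = "cohort_spec")
}

.group_level <- function(group) {
  switch(group, "LRC-" = 0, "HRA-" = 0.5, "ASD" = 1,
         stop("invalid group name: ", group))
}

.synth_channel_labels <- function(n_channels) {
  m <- montage_1020()
  if (n_channels <= length(m)) m[seq_len(n_channels)]
  else c(m, sprintf("E%03d", seq_len(n_channels - length(m))))
}

#' Generate one synthetic EEG recording
#'
#' Each channel is fractional Gaussian noise; channels listed in the spec's
#' effect cells additionally carry a deterministic band-limited tone (fixed
#' frequency at the cell band's center, with slow random phase drift) whose
#' amplitude grows with the severity score, and their noise Hurst parameter
#' shifts with the latent group. Higher severity therefore lowers sample
#' entropy and raises determinism in the designated cells, while
#' `effect_size = 0` removes every group/severity influence.
#'
#' @param group outcome group, one of `"LRC-"`, `"HRA-"`, `"ASD"`.
#' @param css severity score in \[1, 10\].
#' @param spec a [cohort_spec()].
#' @param channel_seed integer seed for this recording's noise and drift.
#' @param age_months visit age; only used when `spec$age_flip` is set, in
#'   which case the group/severity contrast reverses from 12 months on.
#' @return An `eeg_recording` of `n_channels x fs * duration_s` samples.
#' @export
generate_recording <- function(group, css, spec, channel_seed,
                               age_months = NA_real_) {
  stopifnot(inherits(spec, "cohort_spec"))
  glev <- .group_level(group)
  if (!is.numeric(css) || css < 1 || css > 10)
    stop("css must lie in [1, 10]")
  if (spec$duration_s <= 0) stop("non-positive duration")
  n <- as.integer(round(spec$fs * spec$duration_s))
  labels <- .synth_channel_labels(spec$n_channels)
  flip <- spec$age_flip && !is.na(age_months) && age_months >= 12

  es <- spec$effect_size
  sev <- (css - 1) / 9                       # severity weight in [0, 1]
  if (flip) { sev <- 1 - sev; glev <- 1 - glev }
  cells <- spec$effect_cells
  hot_channels <- unique(cells$sensor)
  band_names <- c("high_gamma", "gamma", "beta", "alpha", "theta", "delta")

  samples <- with_seed(channel_seed, function() {
    out <- matrix(0, spec$n_channels, n, dimnames = list(labels, NULL))
    t_idx <- seq_len(n) - 1L
    for (ci in seq_len(spec$n_channels)) {
      lab <- labels[ci]
      H <- 0.55
      if (lab %in% hot_channels)
        H <- min(0.95, H + spec$hurst_shift * es * glev)
      x <- fgn_sim(n, H)
      x <- x / stats::sd(x)
      for (ri in which(cells$sensor == lab)) {
        level <- match(cells$band[ri], band_names)
        edges <- band_frequency_range(level, spec$fs)
        f0 <- sqrt(edges[1] * edges[2])      # band-center tone (geometric)
        drift <- cumsum(stats::rnorm(n, 0, 0.01))
        tone <- sin(2 * pi * f0 * t_idx / spec$fs + drift)
        # project the tone onto the cell's own detail subspace so the
        # planted component re-decomposes entirely into its band (the
        # detail subspaces are orthogonal); a raw tone would leak filter
        # side-lobes into neighboring cells
        tone <- wavelet_bands(tone, spec$fs)$bands[[level]]
        amp <- es * (0.2 + 1.3 * sev)
        x <- x + amp * tone / stats::sd(tone)
      }
      out[ci, ] <- 20 * x / stats::sd(x)     # ~20 uV rms
    }
    out
  })
  eeg_recording(samples, labels, spec$fs, age_months = age_months)
}

.draw_css <- function(group, k) {
  switch(group,
         "LRC-" = stats::runif(k, 1, 2.5),
         "HRA-" = stats::runif(k, 1, 5),
         "ASD"  = stats::runif(k, 4, 10))
}

#' Generate a synthetic cohort
#'
#' Draws a severity score per subject (uniform on \[1, 2.5\] for LRC-,
#' \[1, 5\] for HRA-, \[4, 10\] for ASD, so the high-risk non-ASD group is
#' intermediate and ASD severity is always >= 4), then simulates one
#' recording per subject per visit age with [generate_recording()].
#'
#' @param spec a [cohort_spec()].
#' @return List with `recordings` (list of `eeg_recording`, one per
#'   subject-visit) and `outcomes` (data.frame with columns `subject_id`,
#'   `group`, `css`, `age_months`, one row per subject-visit).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(spec$groups, each = spec$n_per_group)
  n_sub <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_sub))
  draws <- with_seed(spec$seed, function() {
    css <- numeric(n_sub)
    for (g in spec$groups) {
      k <- which(groups == g)
      css[k] <- .draw_css(g, length(k))
    }
    rec_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_sub * length(spec$ages_months))
    list(css = css, rec_seeds = rec_seeds)
  })
  recordings <- vector("list", n_sub * length(spec$ages_months))
  outcomes <- vector("list", length(recordings))
  k <- 0L
  for (ai in seq_along(spec$ages_months)) {
    age <- spec$ages_months[ai]
    for (si in seq_len(n_sub)) {
      k <- k + 1L
      rec <- generate_recording(groups[si], draws$css[si], spec,
                                channel_seed = draws$rec_seeds[k],
                                age_months = age)
      rec$subject_id <- ids[si]
      recordings[[k]] <- rec
      outcomes[[k]] <- data.frame(subject_id = ids[si], group = groups[si],
                                  css = draws$css[si], age_months = age,
                                  stringsAsFactors = FALSE)
    }
  }
  list(recordings = recordings, outcomes = do.call(rbind, outcomes))
}
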