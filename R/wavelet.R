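# Daubechies-4 (8-tap, 4 vanishing moments) orthonormal scaling filter.
# Published constants; highpass via the quadrature-mirror relation.
.db4_lo <- c(-0.010597401785069032, 0.0328830116668852,
             0.030841381835560764, -0.18703481171909309,
             -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965)
.db4_hi <- rev(.db4_lo) * c(-1, 1)[(seq_along(.db4_lo) %% 2) + 1]

.band_labels <- c("high_gamma", "gamma", "beta", "alpha", "theta", "delta")

# one periodized analysis step: returns list(a, d), each length n/2
.dwt_step <- function(x, lo = .db4_lo, hi = .db4_hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(lo)
  idx <- (outer(2 * (seq_len(n / 2) - 1L), 0:(L - 1L), "+") %% n) + 1L
  X <- matrix(x[idx], n / 2, L)
  list(a = drop(X %*% lo), d = drop(X %*% hi))
}

# adjoint of .dwt_step; exact inverse because the periodized transform is
# orthogonal
.idwt_step <- function(a, d, lo = .db4_lo, hi = .db4_hi) {
  n <- 2L * length(a)
  L <- length(lo)
  x <- numeric(n)
  for (j in seq_len(L)) {
    pos <- ((2 * (seq_along(a) - 1L) + (j - 1L)) %% n) + 1L
    contrib <- lo[j] * a + hi[j] * d
    # positions can repeat when n < 2L is impossible here (n >= L); still
    # accumulate defensively
    x[pos] <- x[pos] + contrib
  }
  x
}

# full decomposition to `levels`; x length must be divisible by 2^levels
.dwt <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (k in seq_len(levels)) {
    s <- .dwt_step(a)
    details[[k]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a)
}

.idwt <- function(details, approx) {
  a <- approx
  for (k in rev(seq_along(details))) a <- .idwt_step(a, details[[k]])
  a
}

#' Coarse-grain a time series
#'
#' Block-averaging at a power-of-two scale: output element j is the mean of
#' the j-th non-overlapping block of `scale` consecutive samples. This is
#' the multiscale-entropy scaling procedure; at power-of-two scales it
#' coincides with Haar wavelet approximations under averaging
#' normalization.
#'
#' @param x numeric vector.
#' @param scale power-of-two block length (2, 4, 8, ...).
#' @return Numeric vector of length `floor(length(x) / scale)`.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 2 || bitwAnd(scale, scale - 1L) != 0L)
    stop("scale must be a power of two >= 2")
  if (length(x) < scale) stop("series shorter than scale")
  n_blocks <- length(x) %/% scale
  colMeans(matrix(x[seq_len(n_blocks * scale)], nrow = scale))
}

#' Haar approximation by iterated pairwise averaging
#'
#' Applies `level` steps of pairwise averaging. With the default averaging
#' normalization the result equals `coarse_grain(x, 2^level)` exactly; with
#' `normalization = "orthonormal"` each step uses the 1/sqrt(2) Haar
#' convention instead.
#'
#' @param x numeric vector with `length(x) >= 2^level`.
#' @param level integer depth >= 1.
#' @param normalization `"average"` (default) or `"orthonormal"`.
#' @return Numeric vector of length `floor(length(x) / 2^level)`.
#' @export
haar_approximation <- function(x, level, normalization = c("average",
                                                           "orthonormal")) {
  normalization <- match.arg(normalization)
  level <- as.integer(level)
  if (level < 1) stop("level must be >= 1")
  if (length(x) < 2^level) stop("series too short for requested level")
  w <- if (normalization == "average") 0.5 else 1 / sqrt(2)
  a <- x
  for (k in seq_len(level)) {
    n2 <- length(a) %/% 2L
    a <- w * (a[2 * seq_len(n2) - 1L] + a[2 * seq_len(n2)])
  }
  a
}

#' Nominal frequency range of a dyadic band
#'
#' Level k of the dyadic detail decomposition covers (fs / 2^(k+1),
#' fs / 2^k]: level 1 is the upper half of the spectrum ("high gamma" at
#' 256 Hz: 64-128 Hz), level 6 the lowest band ("delta"). Band labels are
#' names for these power-of-two ranges, not the traditional clinical
#' definitions.
#'
#' @param level integer in 1..6.
#' @param fs sampling rate in Hz.
#' @return Numeric length-2 vector `(low, high)` in Hz.
#' @export
band_frequency_range <- function(level, fs) {
  level <- as.integer(level)
  if (level < 1 || level > 6) stop("level must be in 1..6")
  c(fs / 2^(level + 1), fs / 2^level)
}

#' Dyadic wavelet band decomposition of one channel
#'
#' Six-level discrete wavelet transform with the Daubechies-4 filter; each
#' level's detail coefficients are reconstructed back to signal length in
#' the time domain, so the six band series have equal length and nonlinear
#' measures are comparable across bands. The signal is reflected at its end
#' to the next multiple of 2^6 before the (periodized, orthogonal)
#' transform and the reconstructions are cropped back.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param keep_approx also return the level-6 approximation reconstruction
#'   (sum of details + approximation equals the input).
#' @return List of class `band_set`: `bands` (named list of six numeric
#'   vectors, highest frequency first), `labels`, `ranges_hz` (2 x 6),
#'   `wavelet` and, if requested, `approx`.
#' @export
wavelet_bands <- function(x, fs, keep_approx = FALSE) {
  n <- length(x)
  if (n < 2^6) stop("signal too short for a 6-level decomposition")
  block <- 2L^6L
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect the tail; extension never exceeds n for n >= 64
    ext <- x[n - seq_len(n_pad - n)]
    xp <- c(x, ext)
  } else xp <- x
  dec <- .dwt(xp, 6L)
  bands <- vector("list", 6L)
  zero <- lapply(dec$details, function(d) numeric(length(d)))
  for (k in 1:6) {
    dk <- zero
    dk[[k]] <- dec$details[[k]]
    bands[[k]] <- .idwt(dk, numeric(length(dec$approx)))[seq_len(n)]
  }
  names(bands) <- .band_labels
  out <- list(bands = bands, labels = .band_labels,
              ranges_hz = vapply(1:6, band_frequency_range, numeric(2),
                                 fs = fs),
              wavelet = "db4", fs = fs)
  if (keep_approx)
    out$approx <- .idwt(zero, dec$approx)[seq_len(n)]
  structure(out, class = "band_set")
}
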