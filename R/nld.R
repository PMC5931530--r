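#' Canonical ordering of the nine nonlinear measures
#' @return Character vector of the nine measure names.
#' @export
nld_measure_names <- function() {
  c("RR", "DET", "LAM", "L_max", "L_entr", "L_mean", "TT", "SampE", "DFA")
}

#' Settings for the nonlinear measures
#'
#' Defaults: delay embedding m = 3, tau = 1 with recurrence threshold
#' 0.2 x SD of the analyzed series under the max norm; minimum diagonal and
#' vertical line lengths 2; sample entropy with m = 2, r = 0.2 x SD; DFA
#' over 8 log-spaced box sizes from 16 to N/4 with linear detrending. RQA
#' and sample entropy are evaluated on the leading `max_points` samples of
#' each band series (an 8 s window at 250 Hz); DFA uses the full series.
#'
#' @param m,tau RQA embedding dimension and delay.
#' @param eps_sd RQA threshold in units of the series SD.
#' @param l_min,v_min minimum diagonal / vertical line lengths.
#' @param samp_m,samp_r sample entropy template length and tolerance (SD
#'   units).
#' @param dfa_n_boxes number of DFA box sizes.
#' @param max_points analysis window (samples) for the O(N^2) measures.
#' @return List of class `nld_settings`.
#' @export
nld_settings <- function(m = 3, tau = 1, eps_sd = 0.2, l_min = 2, v_min = 2,
                         samp_m = 2, samp_r = 0.2, dfa_n_boxes = 8,
                         max_points = 2000) {
  structure(list(m = as.integer(m), tau = as.integer(tau), eps_sd = eps_sd,
                 l_min = as.integer(l_min), v_min = as.integer(v_min),
                 samp_m = as.integer(samp_m), samp_r = samp_r,
                 dfa_n_boxes = as.integer(dfa_n_boxes),
                 max_points = as.integer(max_points)),
            class = "nld_settings")
}

.sentinel <- function(reason) {
  structure(NaN, reason = reason)
}

#' Sample entropy
#'
#' -ln(A/B), where B counts pairs of length-`m` templates whose Chebyshev
#' distance is within the tolerance (self-matches excluded) and A the
#' corresponding length-(m+1) counts. Lower values indicate a more regular
#' signal. When no template pair matches (A or B zero), or the tolerance is
#' zero because the series is constant and `r` is specified in SD units,
#' a NaN sentinel with a `reason` attribute is returned instead of an
#' error.
#'
#' @param x numeric series with `length(x) > m + 1`.
#' @param m template length (default 2).
#' @param r tolerance, by default in units of `sd(x)`.
#' @param r_type `"sd"` (tolerance is `r * sd(x)`) or `"absolute"`.
#' @return Sample entropy in nats, or a NaN sentinel.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_type = c("sd", "absolute")) {
  r_type <- match.arg(r_type)
  m <- as.integer(m)
  if (length(x) <= m + 1) stop("series too short for template length m")
  if (r <= 0) stop("tolerance r must be positive")
  tol <- if (r_type == "sd") r * stats::sd(x) else r
  if (!is.finite(tol) || tol <= 0)
    return(.sentinel("zero tolerance (constant series with SD-unit r)"))
  cnt <- sampen_counts_cpp(as.numeric(x), m, tol)
  if (cnt$B == 0) return(.sentinel("no length-m template matches"))
  if (cnt$A == 0) return(.sentinel("no length-(m+1) template matches"))
  -log(cnt$A / cnt$B)
}

.dfa_default_boxes <- function(n, n_boxes = 8) {
  hi <- floor(n / 4)
  if (hi < 16) stop("series too short for DFA box sizes")
  sizes <- unique(round(exp(seq(log(16), log(hi), length.out = n_boxes))))
  sizes[sizes >= 4]
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centered series, splits the profile into
#' non-overlapping boxes of each size, removes a least-squares linear trend
#' per box, and returns the slope of log RMS fluctuation versus log box
#' size. For fractional Gaussian noise the exponent estimates the Hurst
#' parameter; white noise gives ~0.5, a random walk ~1.5.
#'
#' @param x numeric series.
#' @param box_sizes integer window lengths; default 8 log-spaced sizes from
#'   16 to `length(x)/4`.
#' @return The scaling exponent, with attribute `fluctuations`
#'   (data.frame of box size and RMS fluctuation).
#' @export
dfa <- function(x, box_sizes = NULL) {
  n <- length(x)
  if (is.null(box_sizes)) box_sizes <- .dfa_default_boxes(n)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= 4 & box_sizes <= n %/% 2]
  if (length(box_sizes) < 2) stop("fewer than 2 usable box sizes")
  y <- cumsum(x - mean(x))
  fluct <- vapply(box_sizes, function(s) {
    n_box <- n %/% s
    Y <- matrix(y[seq_len(n_box * s)], nrow = s)
    t_s <- seq_len(s)
    X <- cbind(1, t_s)
    # residual-maker applied to all boxes at once
    resid <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
    sqrt(mean(resid^2))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(fluct))
  structure(unname(fit$coefficients[2]),
            fluctuations = data.frame(size = box_sizes, F = fluct))
}

#' Delay embedding of a time series
#'
#' @param x numeric series.
#' @param dim embedding dimension m >= 1.
#' @param tau delay in samples >= 1.
#' @return Matrix of class `embedded_series` (rows are delay vectors,
#'   `nrow = length(x) - (dim - 1) * tau`), with `dim` and `tau`
#'   attributes.
#' @export
embed_series <- function(x, dim, tau = 1) {
  dim <- as.integer(dim); tau <- as.integer(tau)
  stopifnot(dim >= 1, tau >= 1)
  np <- length(x) - (dim - 1L) * tau
  if (np < 1) stop("series too short for requested embedding")
  pts <- vapply(0:(dim - 1L), function(k) x[(1:np) + k * tau], numeric(np))
  pts <- matrix(pts, nrow = np)
  structure(pts, dim_embed = dim, tau = tau, class = "embedded_series")
}

#' Recurrence matrix of an embedded series
#'
#' Entry (i, j) is TRUE when the max-norm distance between delay vectors i
#' and j is at most `epsilon`. The matrix is symmetric with an all-TRUE
#' main diagonal; statistics mask the line of identity when
#' `loi_excluded`.
#'
#' @param e an `embedded_series` (or plain numeric matrix of points).
#' @param epsilon distance threshold > 0.
#' @param loi_excluded mask the main diagonal in downstream statistics.
#' @return Object of class `recurrence_plot`.
#' @export
recurrence_matrix <- function(e, epsilon, loi_excluded = TRUE) {
  stopifnot(epsilon > 0)
  pts <- unclass(e)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1)
  np <- nrow(pts)
  if (np < 1) stop("empty embedding")
  R <- matrix(TRUE, np, np)
  for (k in seq_len(ncol(pts))) {
    dk <- abs(outer(pts[, k], pts[, k], "-")) <= epsilon
    R <- R & dk
  }
  structure(list(matrix = R, epsilon = epsilon, norm = "max",
                 loi_excluded = loi_excluded),
            class = "recurrence_plot")
}

.as_rqa_result <- function(v, settings) {
  structure(c(as.list(v)[c("RR", "DET", "LAM", "L_max", "L_entr",
                           "L_mean", "TT")],
              list(settings = settings,
                   degenerate = isTRUE(attr(v, "degenerate")))),
            class = "rqa_result")
}

#' Recurrence quantification statistics
#'
#' Computes the seven recurrence statistics from a recurrence plot. The
#' line of identity is excluded from the recurrence rate and from line
#' structures (Theiler window 1). Diagonal lines are maximal runs along the
#' off-main diagonals; DET is the fraction of recurrence points on
#' diagonal lines of length >= `l_min`, L_mean/L_max/L_entr summarize the
#' line-length distribution, and the analogous vertical statistics give
#' LAM and TT. A plot with no line structures yields zeros and a
#' `degenerate` flag rather than an error.
#'
#' @param rp a `recurrence_plot` from [recurrence_matrix()].
#' @param l_min minimum diagonal line length (>= 2).
#' @param v_min minimum vertical line length (>= 2).
#' @return Object of class `rqa_result` with elements RR, DET, LAM, L_max,
#'   L_entr, L_mean, TT, the settings used, and a `degenerate` flag.
#' @export
rqa_measures <- function(rp, l_min = 2, v_min = 2) {
  stopifnot(inherits(rp, "recurrence_plot"), l_min >= 2, v_min >= 2)
  np <- nrow(rp$matrix)
  if (l_min > np) stop("l_min exceeds matrix size")
  v <- rqa_matrix_cpp(rp$matrix, as.integer(l_min), as.integer(v_min),
                      rp$loi_excluded)
  .as_rqa_result(v, list(epsilon = rp$epsilon, l_min = l_min, v_min = v_min,
                         loi_excluded = rp$loi_excluded))
}

# streamed equivalent of recurrence_matrix + rqa_measures for long series;
# tested for agreement with the explicit-matrix path
.rqa_series <- function(x, m, tau, epsilon, l_min, v_min) {
  rqa_series_cpp(as.numeric(x), as.integer(m), as.integer(tau), epsilon,
                 as.integer(l_min), as.integer(v_min))
}

#' All nine nonlinear measures for one band series
#'
#' Runs RQA (seven statistics), sample entropy, and DFA with the module's
#' settings. RQA and sample entropy are evaluated on the leading
#' `settings$max_points` samples; DFA on the full series. Degenerate
#' constituents (e.g. a constant band) propagate as NaN sentinels flagged
#' in the `sentinel` attribute rather than as errors.
#'
#' @param band numeric series (one channel's band).
#' @param settings an [nld_settings()] list.
#' @return Named numeric vector of length 9 in the canonical order
#'   [nld_measure_names()], with logical attribute `sentinel`.
#' @export
channel_band_measures <- function(band, settings = nld_settings()) {
  stopifnot(inherits(settings, "nld_settings"))
  w <- band[seq_len(min(length(band), settings$max_points))]
  sdw <- stats::sd(w)
  # essentially-constant bands (e.g. details of a flat channel, which are
  # zero up to rounding noise) are degenerate for SD-scaled tolerances
  degenerate <- !is.finite(sdw) || sdw <= 1e-10
  out <- stats::setNames(rep(NaN, 9), nld_measure_names())
  if (!degenerate) {
    eps <- settings$eps_sd * sdw
    rqa <- .rqa_series(w, settings$m, settings$tau, eps,
                       settings$l_min, settings$v_min)
    out[1:7] <- rqa[c("RR", "DET", "LAM", "L_max", "L_entr", "L_mean", "TT")]
    se <- sample_entropy(w, m = settings$samp_m, r = settings$samp_r)
    out["SampE"] <- as.numeric(se)
  }
  out["DFA"] <- if (stats::sd(band) <= 1e-10) NaN else
    tryCatch(as.numeric(dfa(band)), error = function(e) NaN)
  attr(out, "sentinel") <- !is.finite(out)
  out
}
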