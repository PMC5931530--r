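# Independent brute-force oracles. These re-derive the measures from their
# definitions with naive enumeration and are kept free of any code shared
# with the package internals.

# sample entropy by explicit O(N^2) template comparison
oracle_sampen <- function(x, m, r_abs) {
  N <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r_abs) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NaN)
  -log(A / B)
}

# the seven recurrence statistics by exhaustive run enumeration over an
# explicit symmetric binary matrix, line of identity excluded
oracle_rqa <- function(R, lmin = 2, vmin = 2) {
  np <- nrow(R)
  masked <- R
  diag(masked) <- FALSE
  rr <- sum(masked) / (np^2 - np)
  dl <- integer(0)
  for (d in 1:(np - 1)) {
    v <- R[cbind(1:(np - d), (1 + d):np)]
    r <- rle(v)
    dl <- c(dl, r$lengths[r$values])
  }
  vl <- integer(0)
  for (j in 1:np) {
    r <- rle(masked[, j])
    vl <- c(vl, r$lengths[r$values])
  }
  det <- if (sum(dl) > 0) sum(dl[dl >= lmin]) / sum(dl) else 0
  lsel <- dl[dl >= lmin]
  lmean <- if (length(lsel)) mean(lsel) else 0
  lmax <- if (length(dl)) max(dl) else 0
  lentr <- 0
  if (length(lsel)) {
    p <- as.numeric(table(lsel)) / length(lsel)
    lentr <- -sum(p * log(p))
  }
  vsel <- vl[vl >= vmin]
  lam <- if (sum(vl) > 0) sum(vsel) / sum(vl) else 0
  tt <- if (length(vsel)) mean(vsel) else 0
  c(RR = rr, DET = det, LAM = lam, L_max = lmax, L_entr = lentr,
    L_mean = lmean, TT = tt)
}

# random symmetric recurrence matrix with an all-TRUE diagonal
random_recurrence_matrix <- function(np, density = 0.35) {
  M <- matrix(stats::runif(np * np) < density, np, np)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- TRUE
  M
}

rqa_vec <- function(res) {
  unlist(res[c("RR", "DET", "LAM", "L_max", "L_entr", "L_mean", "TT")])
}

as_recurrence_plot <- function(M, epsilon = 1) {
  structure(list(matrix = M, epsilon = epsilon, norm = "max",
                 loi_excluded = TRUE),
            class = "recurrence_plot")
}

# small montage-shaped recording from raw channel data
toy_recording <- function(n = 500, fs = 250, seed = 1, id = "T1", age = 6) {
  set.seed(seed)
  eeg_recording(matrix(stats::rnorm(19 * n), 19), montage_1020(), fs,
                subject_id = id, age_months = age)
}

# per-cell sample-entropy grid (6 bands x 19 sensors) computed through the
# package decomposition, as a 114-column named feature row
sampe_grid_row <- function(rec, m = 2, r = 0.2) {
  out <- numeric(0)
  for (ci in seq_along(rec$channel_labels)) {
    bs <- wavelet_bands(rec$samples[ci, ], rec$fs)
    v <- vapply(bs$bands, function(b) as.numeric(sample_entropy(b, m, r)),
                numeric(1))
    names(v) <- paste(rec$channel_labels[ci], names(bs$bands), "SampE",
                      sep = ".")
    out <- c(out, v)
  }
  out
}
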