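test_that("sample entropy matches the naive counting oracle exactly", {
  set.seed(11)
  for (n in c(120, 300, 500)) {
    x <- rnorm(n)
    r_abs <- 0.2 * sd(x)
    expect_identical(sample_entropy(x, m = 2, r = 0.2),
                     oracle_sampen(x, 2, r_abs))
    expect_identical(sample_entropy(x, m = 3, r = 0.3),
                     oracle_sampen(x, 3, 0.3 * sd(x)))
  }
})

test_that("sample entropy limiting cases", {
  # strict periodicity with period <= m: every m-match extends
  expect_equal(sample_entropy(rep(c(1, 5), 100), m = 2), 0)
  # constant series: zero with absolute tolerance, sentinel in SD units
  expect_equal(sample_entropy(rep(2, 50), r = 0.5, r_type = "absolute"), 0)
  s <- sample_entropy(rep(2, 50))
  expect_true(is.nan(s))
  expect_match(attr(s, "reason"), "tolerance")
  # regular signal is less entropic than noise at matched variance
  t <- (0:7499) / 250
  sine <- sqrt(2) * sin(2 * pi * 10 * t)
  set.seed(12)
  noise <- rnorm(7500)
  expect_gt(sample_entropy(noise), sample_entropy(sine))
})

test_that("DFA recovers the scaling exponent of known processes", {
  est <- function(gen, k = 20) {
    vapply(seq_len(k), function(i) {
      set.seed(i)
      as.numeric(dfa(gen()))
    }, numeric(1))
  }
  white <- est(function() rnorm(7500))
  expect_lt(abs(mean(white) - 0.5), 0.05)
  walk <- est(function() cumsum(rnorm(7500)), k = 10)
  expect_lt(abs(mean(walk) - 1.5), 0.1)
  fgn8 <- est(function() fgn_sim(7500, 0.8))
  expect_lt(abs(mean(fgn8) - 0.8), 0.07)
  expect_error(dfa(rnorm(7500), box_sizes = c(16, 16)), "box sizes")
})

test_that("delay embedding has the expected geometry", {
  e <- embed_series(c(1, 2, 3, 4), 2, 1)
  expect_equal(unclass(e)[, 1], c(1, 2, 3))
  expect_equal(unclass(e)[, 2], c(2, 3, 4))
  expect_equal(nrow(embed_series(rnorm(7500), 3, 2)), 7496)
  e1 <- embed_series(c(5, 6, 7), 1, 1)
  expect_equal(as.numeric(unclass(e1)), c(5, 6, 7))
  expect_error(embed_series(1:3, 4, 1), "too short")
})

test_that("recurrence matrix is a thresholded max-norm distance", {
  pts <- matrix(c(0, 0, 0.5, 0.4, 3, 3, 3.3, 3.1, 10, 0), ncol = 2,
                byrow = TRUE)
  rp <- recurrence_matrix(structure(pts, class = "embedded_series"), 1)
  D <- unname(as.matrix(stats::dist(pts, method = "maximum")))
  expect_identical(rp$matrix, D <= 1)
  expect_true(isSymmetric(rp$matrix))
  expect_true(all(diag(rp$matrix)))
  # identical points: all ones
  same <- matrix(1, 4, 2)
  expect_true(all(recurrence_matrix(structure(same,
    class = "embedded_series"), 0.1)$matrix))
  expect_error(recurrence_matrix(embed_series(1:5, 2, 1), 0), "epsilon")
})

test_that("RQA statistics agree with the run-enumeration oracle", {
  set.seed(21)
  for (i in 1:50) {
    M <- random_recurrence_matrix(20)
    got <- rqa_vec(rqa_measures(as_recurrence_plot(M)))
    want <- oracle_rqa(M)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("RQA handles saturated and empty plots", {
  full <- rqa_measures(as_recurrence_plot(matrix(TRUE, 5, 5)))
  expect_equal(full$RR, 1)
  expect_equal(full$L_max, 4)
  # corner cells form length-1 diagonals/verticals: 9/10 of recurrence
  # points lie on lines of length >= 2
  expect_equal(full$DET, 0.9)
  expect_equal(full$LAM, 0.9)
  expect_equal(rqa_vec(full), oracle_rqa(matrix(TRUE, 5, 5)))
  empty <- rqa_measures(as_recurrence_plot(diag(5) > 0))
  expect_equal(empty$RR, 0)
  expect_equal(empty$DET, 0)
  expect_equal(empty$LAM, 0)
  expect_true(empty$degenerate)
  expect_error(rqa_measures(as_recurrence_plot(matrix(TRUE, 3, 3)),
                            l_min = 4), "l_min")
})

test_that("streamed series RQA equals the explicit-matrix path", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(150)
    eps <- 0.25 * sd(x)
    rp <- recurrence_matrix(embed_series(x, 3, 1), eps)
    a <- rqa_vec(rqa_measures(rp))
    b <- eegdyn:::.rqa_series(x, 3, 1, eps, 2, 2)[names(a)]
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("recurrence rate is monotone in the threshold", {
  set.seed(23)
  x <- rnorm(200)
  rr <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6), function(eps)
    eegdyn:::.rqa_series(x, 3, 1, eps * sd(x), 2, 2)[["RR"]], numeric(1))
  expect_true(all(diff(rr) >= 0))
})

test_that("bounded measures respect their ranges on random inputs", {
  set.seed(24)
  for (i in 1:40) {
    x <- switch(1 + i %% 4,
                rnorm(300),
                sin(2 * pi * (1:300) / (5 + i)) + 0.2 * rnorm(300),
                cumsum(rnorm(300)),
                rt(300, df = 3))
    v <- channel_band_measures(x, nld_settings(max_points = 300))
    expect_true(all(v[c("RR", "DET", "LAM")] >= 0 &
                      v[c("RR", "DET", "LAM")] <= 1))
    expect_gte(v[["L_entr"]], 0)
    expect_true(v[["L_max"]] >= 0)
  }
})

test_that("the nine measures come out named, ordered, and deterministic", {
  set.seed(25)
  x <- rnorm(2000)
  v1 <- channel_band_measures(x)
  v2 <- channel_band_measures(x)
  expect_identical(names(v1), nld_measure_names())
  expect_identical(as.numeric(v1), as.numeric(v2))
  # sine band: strongly deterministic; noise band far less so
  t <- (0:1999) / 250
  vs <- channel_band_measures(sin(2 * pi * 10 * t) + 0.001 * rnorm(2000))
  vn <- channel_band_measures(rnorm(2000))
  expect_gt(vs[["DET"]], 0.9)
  expect_gt(vs[["DET"]], vn[["DET"]])
  # constant band: SampE sentinel flagged, mask records it
  vc <- channel_band_measures(rep(1, 2000))
  expect_true(is.nan(vc[["SampE"]]))
  expect_true(attr(vc, "sentinel")[["SampE"]])
})
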