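test_that("fGn simulation has the declared second-order structure", {
  set.seed(51)
  # white-noise case: empirical acf near zero, variance near one
  x <- fgn_sim(5000, 0.5)
  expect_lt(abs(var(x) - 1), 0.1)
  # persistent case: positive lag-1 autocorrelation matching theory
  reps <- vapply(1:30, function(i) {
    set.seed(i)
    y <- fgn_sim(2000, 0.8)
    stats::acf(y, plot = FALSE, lag.max = 1)$acf[2]
  }, numeric(1))
  rho1 <- 0.5 * (2^(2 * 0.8) - 2)   # exact fGn lag-1 correlation
  expect_lt(abs(mean(reps) - rho1), 0.03)
})

test_that("recordings are reproducible and dimensionally correct", {
  spec <- cohort_spec()
  a <- generate_recording("LRC-", 1, spec, 7)
  expect_equal(dim(a$samples), c(19, 7500))
  b <- generate_recording("LRC-", 1, spec, 7)
  expect_identical(a$samples, b$samples)
  expect_error(generate_recording("XYZ", 1, spec, 7), "invalid group")
  expect_error(generate_recording("ASD", 12, spec, 7), "css")
  expect_error(cohort_spec(duration_s = 0), "duration_s")
})

test_that("severity moves entropy down and determinism up in effect cells", {
  spec <- cohort_spec(effect_size = 1, duration_s = 8)
  cells <- default_effect_cells()
  cell_means <- function(rec) {
    se <- det <- numeric(0)
    for (i in seq_len(nrow(cells))) {
      ch <- which(rec$channel_labels == cells$sensor[i])
      bs <- wavelet_bands(rec$samples[ch, ], rec$fs)
      mv <- channel_band_measures(bs$bands[[cells$band[i]]],
                                  nld_settings(max_points = 1000))
      se <- c(se, mv[["SampE"]]); det <- c(det, mv[["DET"]])
    }
    c(SampE = mean(se), DET = mean(det))
  }
  asd <- cell_means(generate_recording("ASD", 10, spec, 7))
  lrc <- cell_means(generate_recording("LRC-", 1, spec, 7))
  expect_lt(asd[["SampE"]], lrc[["SampE"]])
  expect_gt(asd[["DET"]], lrc[["DET"]])
  # monotone across the severity scale (seed-averaged cell means)
  traj <- t(vapply(c(1, 4, 7, 10), function(css)
    rowMeans(vapply(11:13, function(sd_i)
      cell_means(generate_recording("ASD", css, spec, sd_i)), numeric(2))),
    numeric(2)))
  # both measures respond weakly at low severity: monotone up to
  # sampling noise, strictly separated across the full scale
  expect_true(all(diff(traj[, "SampE"]) <= 0.005))
  expect_lt(traj[4, "SampE"], traj[1, "SampE"] - 0.02)
  expect_true(all(diff(traj[, "DET"]) >= -0.005))
  expect_gt(traj[4, "DET"], traj[1, "DET"] + 0.02)
})

test_that("the null generator carries no group or severity influence", {
  spec0 <- cohort_spec(effect_size = 0)
  a <- generate_recording("ASD", 10, spec0, 5)
  b <- generate_recording("LRC-", 1, spec0, 5)
  expect_identical(a$samples, b$samples)
})

test_that("null cohorts reject at the nominal rate", {
  # two-sample t on a designated-cell SampE across groups, 200 null cohorts
  spec0 <- cohort_spec(n_per_group = 5, groups = c("LRC-", "ASD"),
                       duration_s = 2, effect_size = 0)
  p <- vapply(1:200, function(i) {
    s <- spec0; s$seed <- i
    coh <- generate_cohort(s)
    v <- vapply(coh$recordings, function(r) {
      bs <- wavelet_bands(r$samples["T7", ], r$fs)
      as.numeric(sample_entropy(bs$bands[["beta"]]))
    }, numeric(1))
    stats::t.test(v ~ coh$outcomes$group)$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
})

test_that("cohort assembly matches the design and is deterministic", {
  spec <- cohort_spec(n_per_group = 5, duration_s = 2, seed = 9)
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 15)
  expect_equal(nrow(coh$outcomes), 15)
  expect_equal(sort(unique(coh$outcomes$group)), sort(spec$groups))
  expect_true(all(coh$outcomes$css >= 1 & coh$outcomes$css <= 10))
  expect_true(all(coh$outcomes$css[coh$outcomes$group == "ASD"] >= 4))
  # HRA- severity intermediate in distribution
  m <- tapply(coh$outcomes$css, coh$outcomes$group, mean)
  expect_true(m[["LRC-"]] < m[["HRA-"]] && m[["HRA-"]] < m[["ASD"]])
  coh2 <- generate_cohort(spec)
  expect_identical(coh$outcomes, coh2$outcomes)
  expect_identical(coh$recordings[[3]]$samples, coh2$recordings[[3]]$samples)
  # multiple ages: one recording per subject per age
  spec2 <- cohort_spec(n_per_group = 2, ages_months = c(6, 9),
                       duration_s = 2)
  coh3 <- generate_cohort(spec2)
  expect_length(coh3$recordings, 12)
  expect_equal(sum(coh3$outcomes$age_months == 9), 6)
  expect_error(generate_cohort(cohort_spec(groups = character(0))), "group")
})

test_that("the age flip reverses the group contrast after 12 months", {
  spec <- cohort_spec(effect_size = 1.5, duration_s = 4, age_flip = TRUE)
  cell_se <- function(rec) {
    bs <- wavelet_bands(rec$samples["T7", ], rec$fs)
    as.numeric(sample_entropy(bs$bands[["beta"]]))
  }
  d_young <- cell_se(generate_recording("ASD", 9, spec, 3, age_months = 6)) -
    cell_se(generate_recording("LRC-", 1, spec, 3, age_months = 6))
  d_old <- cell_se(generate_recording("ASD", 9, spec, 3, age_months = 18)) -
    cell_se(generate_recording("LRC-", 1, spec, 3, age_months = 18))
  expect_lt(d_young, 0)
  expect_gt(d_old, 0)
})
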