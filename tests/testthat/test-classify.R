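test_that("distance-to-severity map is affine, clipped, and monotone", {
  expect_equal(css_from_distance(c(-2, 2), c(1, 10), 0), 5.5)
  expect_equal(css_from_distance(c(-2, 2), c(1, 10), 50), 10)
  expect_equal(css_from_distance(c(-2, 2), c(1, 10), -50), 1)
  d <- seq(-5, 5, by = 0.25)
  est <- css_from_distance(c(-1, 0, 1, 2), c(2, 3, 6, 8), d)
  expect_true(all(diff(est) >= 0))
  expect_true(all(est >= 1 & est <= 10))
  expect_error(css_from_distance(c(1, 1), c(2, 3), 0), "zero-variance")
})

test_that("severity labels respect the uncertainty zone", {
  expect_equal(label_with_uncertainty(c(4.0, 5.2, 2.0, 3.5, 4.5)),
               c("uncertain", "ASD", "not-ASD", "not-ASD", "ASD"))
  expect_equal(label_with_uncertainty(c(3.9, 4.0, 4.1), uncertainty = FALSE),
               c("not-ASD", "ASD", "ASD"))
})

test_that("report arithmetic follows the standard definitions", {
  mk <- function(group, label) data.frame(group = group,
                                          predicted_label = label)
  r <- mk(rep(c("ASD", "LRC-"), each = 10),
          c(rep("ASD", 9), "not-ASD", rep("not-ASD", 9), "ASD"))
  rep1 <- classification_metrics(r)
  expect_equal(rep1$sensitivity, 0.9)
  expect_equal(rep1$specificity, 0.9)
  expect_equal(rep1$ppv, 0.9)
  perfect <- classification_metrics(mk(c("ASD", "ASD", "LRC-"),
                                       c("ASD", "ASD", "not-ASD")))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv),
               c(1, 1, 1))
  # uncertain rows are excluded from counts and reported
  r2 <- mk(c(rep("HRA-", 7), rep(c("ASD", "LRC-"), c(20, 19))),
           c(rep("uncertain", 7), rep("ASD", 20), rep("not-ASD", 19)))
  rep2 <- classification_metrics(r2)
  expect_equal(rep2$n_uncertain, 7)
  expect_equal(rep2$tp + rep2$fp + rep2$tn + rep2$fn, 39)
  # zero denominator yields NaN, not an error
  rep3 <- classification_metrics(mk(c("LRC-", "LRC-"),
                                    c("not-ASD", "not-ASD")))
  expect_true(is.nan(rep3$sensitivity))
})

test_that("RFE recovers planted informative features", {
  overlaps <- vapply(1:20, function(s) {
    coh <- synth_feature_cohort(n_per = 20, p = 100, p_inf = 10, sep = 3,
                                seed = s)
    prep <- eegdyn:::.fit_prep(coh$X)
    sel <- rfe_select(prep$X, factor(coh$outcomes$group), rfe_min = 10)
    length(intersect(sel, 1:10))
  }, numeric(1))
  expect_gte(median(overlaps), 8)
  expect_true(all(overlaps >= 0))
})

test_that("RFE never returns an empty set and keeps duplicated signal", {
  coh <- synth_feature_cohort(n_per = 10, p = 30, p_inf = 0, sep = 0,
                              seed = 4)
  sel <- rfe_select(coh$X, factor(coh$outcomes$group))
  expect_gt(length(sel), 0)
  # duplicate an informative column; at least one copy must survive
  coh2 <- synth_feature_cohort(n_per = 15, p = 40, p_inf = 5, sep = 3,
                               seed = 5)
  X2 <- cbind(coh2$X, dup = coh2$X[, 1])
  sel2 <- rfe_select(X2, factor(coh2$outcomes$group), rfe_min = 8)
  expect_true(any(c(1, ncol(X2)) %in% sel2))
  expect_error(rfe_select(coh$X, factor(rep("ASD", 20))), "two classes")
})

test_that("leave-one-out prediction separates a separable cohort", {
  coh <- synth_feature_cohort(n_per = 10, p = 60, p_inf = 12, sep = 3,
                              seed = 6, groups = c("LRC-", "HRA-", "ASD"))
  res <- loo_predict(coh$X, coh$outcomes,
                     classify_settings(n_features = 12))
  expect_equal(nrow(res), 30)
  expect_true(all(res$css_estimate >= 1 & res$css_estimate <= 10))
  keep <- res$group %in% c("ASD", "LRC-")
  bin <- ifelse(res$css_estimate[keep] >= 4, "ASD", "not-ASD")
  truth <- ifelse(res$group[keep] == "ASD", "ASD", "not-ASD")
  expect_equal(mean(bin == truth), 1)
  # HRA- severity intermediate between the trained groups
  m <- tapply(res$css_estimate, res$group, mean)
  expect_true(m[["LRC-"]] < m[["HRA-"]] && m[["HRA-"]] < m[["ASD"]])
  # uncertainty zone is exactly the open interval (3.5, 4.5)
  zone <- res$css_estimate > 3.5 & res$css_estimate < 4.5
  expect_identical(res$predicted_label == "uncertain", zone)
})

test_that("a left-out subject's outcome never leaks into its own score", {
  coh <- synth_feature_cohort(n_per = 6, p = 30, p_inf = 8, sep = 3,
                              seed = 7)
  st <- classify_settings(n_features = 8)
  base <- loo_predict(coh$X, coh$outcomes, st)
  # flip subject 1's label and severity: its own distance must not move
  oc2 <- coh$outcomes
  oc2$group[1] <- "ASD"
  oc2$css[1] <- 9.5
  mod <- loo_predict(coh$X, oc2, st)
  expect_equal(mod$decision_distance[1], base$decision_distance[1])
  expect_equal(mod$css_estimate[1], base$css_estimate[1])
})

test_that("null cohorts classify at chance", {
  acc <- vapply(1:20, function(s) {
    coh <- synth_feature_cohort(n_per = 8, p = 30, p_inf = 0, sep = 0,
                                seed = 100 + s)
    eegdyn:::.loo_accuracy(coh$X, coh$outcomes,
                           classify_settings(rfe = FALSE))
  }, numeric(1))
  expect_gt(mean(acc), 0.3)
  expect_lt(mean(acc), 0.7)
})

test_that("permutation p-values separate signal from null", {
  coh <- synth_feature_cohort(n_per = 8, p = 30, p_inf = 10, sep = 3,
                              seed = 8)
  pp <- permutation_pvalue(coh$X, coh$outcomes, n_trials = 50, seed = 2,
                           settings = classify_settings(n_features = 10))
  expect_lte(pp$p_value, 2 / 51)
  expect_equal(pp$observed, 1)
  # single-trial add-one estimator can only be 1/2 or 1
  p1 <- permutation_pvalue(coh$X, coh$outcomes, n_trials = 1, seed = 3,
                           settings = classify_settings(n_features = 10))
  expect_true(p1$p_value %in% c(0.5, 1.0))
  # shuffles are seed-reproducible
  pp2 <- permutation_pvalue(coh$X, coh$outcomes, n_trials = 10, seed = 2,
                            settings = classify_settings(n_features = 10))
  pp3 <- permutation_pvalue(coh$X, coh$outcomes, n_trials = 10, seed = 2,
                            settings = classify_settings(n_features = 10))
  expect_identical(pp2$null_accuracies, pp3$null_accuracies)
})
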