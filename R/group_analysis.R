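#' Bonferroni cutoff for the sensor x band x measure family
#'
#' The significance gate used in the group-difference maps: 0.05 spread
#' over the 1026 features, stated as the literal 5e-5.
#' @export
bonferroni_alpha <- 5e-5

#' Scalp region presets
#'
#' Sensor groups used in the developmental-trajectory summaries. Two
#' frontal sets are provided (a 5- and a 6-sensor variant, both in use in
#' the literature for this analysis).
#' @return Named list of sensor-label vectors.
#' @export
region_presets <- function() {
  list(left_temporal = "T7",
       right_temporal_parietal = c("T8", "P4", "P8"),
       left_lateral_frontal = "F7",
       frontal_5 = c("Fp1", "F7", "Fz", "F8", "Fp2"),
       frontal_6 = c("F7", "F3", "Fp1", "Fp2", "F4", "F8"),
       posterior = c("O1", "O2"))
}

#' Frequency-band presets
#' @return Named list of band-label vectors.
#' @export
band_presets <- function() {
  list(beta_gamma = c("beta", "gamma"),
       theta_through_gamma = c("theta", "alpha", "beta", "gamma"),
       delta = "delta")
}

.measure_columns <- function(feature_names, measure) {
  parts <- strsplit(feature_names, ".", fixed = TRUE)
  ok <- vapply(parts, function(p) p[3] == measure, logical(1))
  if (!any(ok)) stop("no columns found for measure ", measure)
  data.frame(column = which(ok),
             sensor = vapply(parts[ok], `[`, character(1), 1),
             band = vapply(parts[ok], `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Sensor x band group-difference map for one measure
#'
#' For every sensor/band cell of the chosen measure, a two-sided Welch
#' t-test compares the two groups' feature values; a cell is flagged
#' significant when p falls below the Bonferroni cutoff. The direction is
#' +1 where the first (ASD) group mean exceeds the second, -1 otherwise.
#' Cells with zero variance in both groups are reported as p = 1.
#'
#' @param features_asd sessions x features matrix of the ASD group.
#' @param features_ref matrix of the comparison group (same columns).
#' @param measure one of [nld_measure_names()].
#' @param age_months visit age annotation (optional).
#' @param alpha significance cutoff (default [bonferroni_alpha]).
#' @param test `"welch"` (default) or `"wilcoxon"` (Mann-Whitney).
#' @return Object of class `difference_map`: data.frame `cells` with
#'   columns sensor, band, direction, p_value, significant, plus the
#'   measure, age and threshold.
#' @export
difference_map <- function(features_asd, features_ref, measure,
                           age_months = NA, alpha = bonferroni_alpha,
                           test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (nrow(features_asd) < 3 || nrow(features_ref) < 3)
    stop("need at least 3 subjects per group")
  cols <- .measure_columns(colnames(features_asd), measure)
  res <- lapply(seq_len(nrow(cols)), function(i) {
    a <- features_asd[, cols$column[i]]
    b <- features_ref[, cols$column[i]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    md <- mean(a) - mean(b)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else
      tryCatch(
        if (test == "welch")
          stats::t.test(a, b, var.equal = FALSE)$p.value
        else
          stats::wilcox.test(a, b, exact = FALSE)$p.value,
        error = function(e) 1)
    c(direction = sign(md), p_value = p)
  })
  res <- do.call(rbind, res)
  cells <- data.frame(sensor = cols$sensor, band = cols$band,
                      direction = res[, "direction"],
                      p_value = res[, "p_value"],
                      significant = res[, "p_value"] < alpha,
                      stringsAsFactors = FALSE)
  structure(list(measure = measure, age_months = age_months,
                 threshold = alpha, cells = cells),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  n_sig <- sum(x$cells$significant)
  cat(sprintf("<difference_map> %s (age %s): %d of %d cells below p < %g\n",
              x$measure, x$age_months, n_sig, nrow(x$cells), x$threshold))
  invisible(x)
}

#' Regional developmental trajectory of one measure
#'
#' For each visit age: the measure is averaged over the listed sensors and
#' bands within each subject, then across the group's subjects; a 95%
#' confidence band comes from a seed-controlled percentile bootstrap over
#' subjects.
#'
#' @param features sessions x features matrix (all ages pooled).
#' @param outcomes aligned data.frame with `subject_id`, `group`,
#'   `age_months`.
#' @param group outcome group to trace.
#' @param region_sensors sensor labels (see [region_presets()]).
#' @param bands band labels (see [band_presets()]).
#' @param measure one of [nld_measure_names()].
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return Object of class `trajectory_curve`: data.frame `curve` with
#'   age, n, mean, ci_low, ci_high, plus the region/band/measure
#'   definition.
#' @export
regional_trajectory <- function(features, outcomes, group, region_sensors,
                                bands, measure, n_boot = 2000, seed = 1,
                                conf = 0.95) {
  if (length(region_sensors) < 1 || length(bands) < 1)
    stop("region and band lists must be non-empty")
  cols <- .measure_columns(colnames(features), measure)
  cols <- cols[cols$sensor %in% region_sensors & cols$band %in% bands, ]
  if (nrow(cols) == 0) stop("no feature cells match the region/band lists")
  keep <- outcomes$group == group
  vals <- rowMeans(features[keep, cols$column, drop = FALSE])
  ages <- outcomes$age_months[keep]
  uages <- sort(unique(ages))
  if (length(uages) < 2) stop("need at least 2 visit ages")
  alpha2 <- (1 - conf) / 2
  curve <- with_seed(seed, function() {
    do.call(rbind, lapply(uages, function(a) {
      v <- vals[ages == a]
      if (length(v) < 3) stop("need at least 3 subjects per age (age ", a, ")")
      bm <- replicate(n_boot, mean(sample(v, replace = TRUE)))
      q <- stats::quantile(bm, c(alpha2, 1 - alpha2), names = FALSE)
      data.frame(age = a, n = length(v), mean = mean(v),
                 ci_low = min(q[1], mean(v)), ci_high = max(q[2], mean(v)))
    }))
  })
  structure(list(group = group, region_sensors = region_sensors,
                 bands = bands, measure = measure, curve = curve),
            class = "trajectory_curve")
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("<trajectory_curve> %s %s [%s x %s]\n", x$group, x$measure,
              paste(x$region_sensors, collapse = "+"),
              paste(x$bands, collapse = "+")))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
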