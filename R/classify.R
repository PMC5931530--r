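# Classification protocol: ASD vs LRC- training with leave-one-out
# cross-validation, HRA- scored against the full ASD/LRC- model, severity
# estimated from the signed decision-function value. Everything that is
# fitted -- imputation medians, z-score statistics, feature elimination,
# the SVM, the severity map -- is fold-local, so a subject's own data never
# influences the model that scores it.

#' Settings for the classification protocol
#'
#' @param rfe run recursive feature elimination inside every fold.
#' @param rfe_min smallest candidate subset size in the halving schedule.
#' @param rfe_cv folds of the deterministic internal cross-validation used
#'   to pick the subset size.
#' @param n_features fixed subset size (skips the internal CV); NULL picks
#'   the size by CV.
#' @param uncertainty label estimates in the open zone (3.5, 4.5) as
#'   `"uncertain"` instead of forcing a binary call.
#' @return List of class `classify_settings`.
#' @export
classify_settings <- function(rfe = TRUE, rfe_min = 16, rfe_cv = 3,
                              n_features = NULL, uncertainty = TRUE) {
  structure(list(rfe = isTRUE(rfe), rfe_min = as.integer(rfe_min),
                 rfe_cv = as.integer(rfe_cv), n_features = n_features,
                 uncertainty = isTRUE(uncertainty)),
            class = "classify_settings")
}

# column medians over finite entries, computed only for the columns that
# contain sentinels; all-sentinel columns fall back to 0
.col_medians <- function(X, cols) {
  med <- numeric(ncol(X))
  for (j in cols) {
    v <- stats::median(X[is.finite(X[, j]), j])
    med[j] <- if (is.finite(v)) v else 0
  }
  med
}

.apply_prep <- function(X, prep) {
  bad <- !is.finite(X)
  if (any(bad)) {
    for (j in which(colSums(bad) > 0L)) X[bad[, j], j] <- prep$med[j]
  }
  sweep(sweep(X, 2L, prep$mu), 2L, prep$sigma, "/")
}

.fit_prep <- function(X) {
  bad <- !is.finite(X)
  need <- which(colSums(bad) > 0L)
  med <- .col_medians(X, need)
  for (j in need) X[bad[, j], j] <- med[j]
  n <- nrow(X)
  mu <- colMeans(X)
  sigma <- sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  prep <- list(med = med, mu = mu, sigma = sigma)
  list(prep = prep, X = sweep(sweep(X, 2L, mu), 2L, sigma, "/"))
}

# squared hyperplane weights of a linear SVM: the RFE ranking criterion
.linear_svm_importance <- function(X, y) {
  fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)^2
}

# deterministic stratified folds: round-robin within class in row order,
# so repeated runs share the identical fold structure without any RNG
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.cv_accuracy <- function(X, y, k) {
  k <- min(k, min(table(y)))
  if (k < 2) return(NA_real_)
  fold <- .stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      scale = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Recursive feature elimination with a linear-SVM ranking
#'
#' Features are ranked by the squared weights of a linear-kernel SVM and
#' the lowest-ranked half is dropped repeatedly, yielding a nested halving
#' schedule of candidate subsets down to `rfe_min`. The returned subset is
#' the candidate with the best internal cross-validated accuracy of the
#' radial-kernel classifier (ties to the smaller subset), or the top
#' `n_features` features when a fixed size is requested. The result is
#' never empty, and the procedure is deterministic: fold structure is
#' round-robin by class, no randomness is consumed.
#'
#' @param features training matrix (sessions x features), already prepared
#'   (finite values; callers inside the pipeline impute and scale first).
#' @param labels two-level factor (or coercible) of outcomes.
#' @param rfe_min smallest candidate size.
#' @param rfe_cv internal CV fold count.
#' @param n_features fixed subset size, or NULL.
#' @return Sorted integer vector of selected column indices.
#' @export
rfe_select <- function(features, labels, rfe_min = 16, rfe_cv = 3,
                       n_features = NULL) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("rfe_select requires exactly two classes")
  p <- ncol(features)
  active <- seq_len(p)
  candidates <- list(active)
  while (length(active) > rfe_min) {
    imp <- .linear_svm_importance(features[, active, drop = FALSE], y)
    keep_n <- max(rfe_min, ceiling(length(active) / 2))
    if (keep_n == length(active)) keep_n <- rfe_min
    active <- active[order(imp, decreasing = TRUE)[seq_len(keep_n)]]
    candidates <- c(candidates, list(sort(active)))
  }
  if (!is.null(n_features)) {
    n_features <- min(n_features, p)
    sizes <- vapply(candidates, length, integer(1))
    pick <- candidates[[which(sizes >= n_features)[sum(sizes >= n_features)]]]
    if (length(pick) > n_features) {
      imp <- .linear_svm_importance(features[, pick, drop = FALSE], y)
      pick <- pick[order(imp, decreasing = TRUE)[seq_len(n_features)]]
    }
    return(sort(pick))
  }
  acc <- vapply(candidates, function(idx)
    .cv_accuracy(features[, idx, drop = FALSE], y, rfe_cv), numeric(1))
  if (all(is.na(acc))) return(sort(candidates[[length(candidates)]]))
  best <- max(acc, na.rm = TRUE)
  # smallest subset achieving the best score
  sizes <- vapply(candidates, length, integer(1))
  ok <- which(!is.na(acc) & acc >= best - 1e-12)
  sort(candidates[[ok[which.min(sizes[ok])]]])
}

#' Map a decision distance to a severity estimate
#'
#' Least-squares affine fit of the training severity scores on the
#' training signed decision distances, applied to a new distance and
#' clipped to the severity scale \[1, 10\]. The fit is computed within the
#' training fold only.
#'
#' @param distances training signed distances.
#' @param css_train training severity scores.
#' @param d_new distance(s) to map.
#' @return Severity estimate(s) in \[1, 10\].
#' @export
css_from_distance <- function(distances, css_train, d_new) {
  if (length(distances) < 2) stop("need at least 2 training distances")
  if (stats::sd(distances) == 0) stop("zero-variance training distances")
  fit <- stats::lm.fit(cbind(1, distances), css_train)
  est <- fit$coefficients[1] + fit$coefficients[2] * d_new
  pmin(pmax(unname(est), 1), 10)
}

#' Label a severity estimate
#'
#' With the uncertainty zone active, estimates in the open interval
#' (3.5, 4.5) are `"uncertain"`, at or above 4.5 `"ASD"`, at or below 3.5
#' `"not-ASD"`. In binary mode the clinical rule applies directly: ASD iff
#' the estimate is at least 4.
#'
#' @param css_estimate numeric severity estimate(s) in \[1, 10\].
#' @param uncertainty use the uncertainty zone (default TRUE).
#' @return Character vector of labels.
#' @export
label_with_uncertainty <- function(css_estimate, uncertainty = TRUE) {
  if (uncertainty) {
    ifelse(css_estimate >= 4.5, "ASD",
           ifelse(css_estimate <= 3.5, "not-ASD", "uncertain"))
  } else {
    ifelse(css_estimate >= 4, "ASD", "not-ASD")
  }
}

# fit the full fold pipeline on (X_tr, y_tr, css_tr) and score X_te;
# returns signed distances (ASD positive) and severity estimates
.fit_fold <- function(X_tr, y_tr, css_tr, X_te, settings) {
  prep <- .fit_prep(X_tr)
  Xtr <- prep$X
  Xte <- .apply_prep(X_te, prep$prep)
  y <- factor(y_tr, levels = c("not-ASD", "ASD"))
  if (any(table(y) < 1)) stop("single-class training fold")
  sel <- seq_len(ncol(Xtr))
  if (settings$rfe) {
    sel <- rfe_select(Xtr, y, rfe_min = settings$rfe_min,
                      rfe_cv = settings$rfe_cv,
                      n_features = settings$n_features)
  }
  fit <- e1071::svm(Xtr[, sel, drop = FALSE], y, kernel = "radial",
                    scale = FALSE)
  d_tr <- as.numeric(attr(stats::predict(fit, Xtr[, sel, drop = FALSE],
                                         decision.values = TRUE),
                          "decision.values"))
  d_te <- as.numeric(attr(stats::predict(fit, Xte[, sel, drop = FALSE],
                                         decision.values = TRUE),
                          "decision.values"))
  # orient the axis so ASD lies on the positive side
  if (mean(d_tr[y == "ASD"]) < mean(d_tr[y == "not-ASD"])) {
    d_tr <- -d_tr
    d_te <- -d_te
  }
  css_te <- css_from_distance(d_tr, css_tr, d_te)
  list(distance = d_te, css = css_te, n_selected = length(sel))
}

#' Leave-one-out outcome prediction
#'
#' ASD and LRC- subjects form the training population: each is scored by a
#' model fitted on all the others (leave-one-out). HRA- subjects are
#' scored by the model fitted on the full ASD/LRC- set. Every fit runs the
#' complete fold pipeline (median imputation, z-scoring, recursive feature
#' elimination, radial-kernel SVM, affine severity map), so no statistic
#' of a fold ever involves the subject it scores. All rows must come from
#' one visit age; visits at different ages are treated as independent and
#' classified in separate calls.
#'
#' @param features sessions x features numeric matrix.
#' @param outcomes data.frame aligned with `features` rows, with columns
#'   `subject_id`, `group` (`"LRC-"`, `"HRA-"`, `"ASD"`), `css`,
#'   `age_months`.
#' @param settings a [classify_settings()] list.
#' @return data.frame with one row per subject: `subject_id`,
#'   `age_months`, `group`, `true_css`, `decision_distance`,
#'   `css_estimate`, `predicted_label`.
#' @export
loo_predict <- function(features, outcomes, settings = classify_settings()) {
  stopifnot(nrow(features) == nrow(outcomes))
  ages <- unique(outcomes$age_months)
  if (length(ages[!is.na(ages)]) > 1)
    stop("loo_predict takes one visit age at a time")
  grp <- outcomes$group
  is_train <- grp %in% c("ASD", "LRC-")
  y_all <- ifelse(grp == "ASD", "ASD", "not-ASD")
  if (sum(grp == "ASD") < 3 || sum(grp == "LRC-") < 3)
    stop("need at least 3 subjects in each training class")

  distance <- css_est <- rep(NA_real_, nrow(features))
  tr_idx <- which(is_train)
  for (i in tr_idx) {
    fold <- setdiff(tr_idx, i)
    r <- .fit_fold(features[fold, , drop = FALSE], y_all[fold],
                   outcomes$css[fold], features[i, , drop = FALSE],
                   settings)
    distance[i] <- r$distance
    css_est[i] <- r$css
  }
  ho_idx <- which(!is_train)
  if (length(ho_idx) > 0) {
    r <- .fit_fold(features[tr_idx, , drop = FALSE], y_all[tr_idx],
                   outcomes$css[tr_idx],
                   features[ho_idx, , drop = FALSE], settings)
    distance[ho_idx] <- r$distance
    css_est[ho_idx] <- r$css
  }
  data.frame(subject_id = outcomes$subject_id,
             age_months = outcomes$age_months,
             group = grp, true_css = outcomes$css,
             decision_distance = distance, css_estimate = css_est,
             predicted_label = label_with_uncertainty(css_est,
                                                      settings$uncertainty),
             stringsAsFactors = FALSE)
}

#' Classification report
#'
#' Confusion counts and the standard rates (sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP)) with ASD as the positive
#' class. Subjects labeled `"uncertain"` are excluded from the counts when
#' `exclude_uncertain` is set and reported in `n_uncertain`. Zero
#' denominators yield NaN rather than an error.
#'
#' @param results data.frame from [loo_predict()].
#' @param exclude_uncertain drop uncertain predictions from the counts.
#' @return List of class `classification_report`.
#' @export
classification_metrics <- function(results, exclude_uncertain = TRUE) {
  stopifnot(nrow(results) > 0)
  unc <- results$predicted_label == "uncertain"
  n_uncertain <- sum(unc)
  use <- if (exclude_uncertain) results[!unc, , drop = FALSE] else results
  truth <- use$group == "ASD"
  pred <- use$predicted_label == "ASD"
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  rate <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  structure(list(sensitivity = rate(tp, fn), specificity = rate(tn, fp),
                 ppv = rate(tp, fp), tp = tp, fp = fp, tn = tn, fn = fn,
                 n_uncertain = n_uncertain, n_total = nrow(results)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "sens %.3f  spec %.3f  ppv %.3f  (TP %d FP %d TN %d FN %d; %d uncertain of %d)\n",
    x$sensitivity, x$specificity, x$ppv, x$tp, x$fp, x$tn, x$fn,
    x$n_uncertain, x$n_total))
  invisible(x)
}

# binary leave-one-out accuracy over the ASD/LRC- training population: the
# permutation test statistic
.loo_accuracy <- function(features, outcomes, settings) {
  s <- settings
  s$uncertainty <- FALSE
  res <- loo_predict(features, outcomes, s)
  keep <- res$group %in% c("ASD", "LRC-")
  truth <- ifelse(res$group[keep] == "ASD", "ASD", "not-ASD")
  mean(res$predicted_label[keep] == truth)
}

#' Permutation significance of the classification
#'
#' Reruns the identical leave-one-out pipeline under `n_trials` random
#' permutations of the outcome labels (each subject's label and severity
#' score travel together) and reports the add-one empirical p-value
#' `(1 + #[accuracy_perm >= accuracy_observed]) / (1 + n_trials)`, which
#' is never exactly zero.
#'
#' @param features sessions x features matrix (ASD and LRC- rows are used).
#' @param outcomes aligned outcomes data.frame.
#' @param n_trials number of label shuffles (default 100).
#' @param seed integer seed for the shuffles.
#' @param settings a [classify_settings()] list.
#' @return List: `p_value`, `observed` accuracy, `n_exceed` (shuffles at or
#'   above the observed accuracy), `null_accuracies`.
#' @export
permutation_pvalue <- function(features, outcomes, n_trials = 100, seed = 1,
                               settings = classify_settings()) {
  stopifnot(n_trials >= 1)
  keep <- outcomes$group %in% c("ASD", "LRC-")
  X <- features[keep, , drop = FALSE]
  oc <- outcomes[keep, , drop = FALSE]
  observed <- .loo_accuracy(X, oc, settings)
  perms <- with_seed(seed, function()
    replicate(n_trials, sample.int(nrow(oc)), simplify = FALSE))
  null_acc <- vapply(perms, function(p) {
    oc_p <- oc
    oc_p$group <- oc$group[p]
    oc_p$css <- oc$css[p]
    .loo_accuracy(X, oc_p, settings)
  }, numeric(1))
  n_exceed <- sum(null_acc >= observed)
  list(p_value = (1 + n_exceed) / (1 + n_trials), observed = observed,
       n_exceed = n_exceed, null_accuracies = null_acc)
}
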