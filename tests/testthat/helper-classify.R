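# Synthetic feature-space cohorts for classifier tests: severity-linked
# informative columns plus pure-noise columns, bypassing signal
# featurization so the protocol can be exercised cheaply.
synth_feature_cohort <- function(n_per = 10, p = 40, p_inf = 10, sep = 3,
                                 seed = 1, groups = c("LRC-", "ASD")) {
  set.seed(seed)
  grp <- rep(groups, each = n_per)
  n <- length(grp)
  css <- ifelse(grp == "ASD", runif(n, 4, 10),
                ifelse(grp == "HRA-", runif(n, 1, 5), runif(n, 1, 2.5)))
  X <- matrix(rnorm(n * p), n, p)
  drive <- sep * (css - mean(css)) / sd(css)
  for (j in seq_len(p_inf)) X[, j] <- X[, j] + drive
  colnames(X) <- c(sprintf("inf%d", seq_len(p_inf)),
                   sprintf("noise%d", seq_len(p - p_inf)))
  list(X = X,
       outcomes = data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                             group = grp, css = css, age_months = 6,
                             stringsAsFactors = FALSE))
}
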