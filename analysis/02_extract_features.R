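#!/usr/bin/env Rscript
# Stage 2: read the cohort EDFs, normalize them to the analysis form
# (19-channel montage, 250 Hz, leading 30 s segment), and extract the
# 1026 nonlinear features per session into one CSV per visit age.

suppressPackageStartupMessages(library(eegdyn))

in_dir <- "results/cohort"
out_dir <- "results/features"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

outcomes <- read.csv(file.path(in_dir, "outcomes.csv"))
settings <- nld_settings()

for (age in sort(unique(outcomes$age_months))) {
  oc <- outcomes[outcomes$age_months == age, ]
  recs <- lapply(seq_len(nrow(oc)), function(i) {
    rec <- read_edf(file.path(in_dir, sprintf("%s_m%02d.edf",
                                              oc$subject_id[i], age)))
    rec <- resample_to_250(select_montage(rec))
    rec <- extract_segment(rec, 30)
    rec$subject_id <- oc$subject_id[i]
    rec$age_months <- age
    rec
  })
  X <- cohort_features(recs, settings, expect_duration_s = 30)
  n_sent <- sum(!is.finite(X))
  path <- file.path(out_dir, sprintf("features_m%02d.csv", age))
  write_feature_table(X, oc, path)
  cat(sprintf("age %2d mo: %d sessions x %d features -> %s (%d sentinel cells)\n",
              age, nrow(X), ncol(X), path, n_sent))
}
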