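#!/usr/bin/env Rscript
# Stage 5: developmental trajectories of sample entropy and determinism in
# the preset scalp regions, per outcome group, with bootstrap confidence
# bands. Mirrors the regional summaries of the classification study:
# SampE in left temporal (beta+gamma), right temporal-parietal
# (theta-gamma) and posterior delta; DET in the frontal regions.

suppressPackageStartupMessages(library(eegdyn))

feat_dir <- "results/features"
out_dir <- "results/trajectories"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- sort(list.files(feat_dir, "^features_m", full.names = TRUE))
tabs <- lapply(files, read_feature_table)
features <- do.call(rbind, lapply(tabs, `[[`, "features"))
outcomes <- do.call(rbind, lapply(tabs, `[[`, "outcomes"))

panels <- list(
  list(region = "left_temporal", bands = "beta_gamma", measure = "SampE"),
  list(region = "right_temporal_parietal", bands = "theta_through_gamma",
       measure = "SampE"),
  list(region = "left_lateral_frontal", bands = "theta_through_gamma",
       measure = "DET"),
  list(region = "frontal_6", bands = "beta_gamma", measure = "DET"),
  list(region = "posterior", bands = "delta", measure = "SampE"))

rows <- list()
for (p in panels) {
  sensors <- region_presets()[[p$region]]
  bands <- band_presets()[[p$bands]]
  for (g in c("LRC-", "HRA-", "ASD")) {
    tc <- regional_trajectory(features, outcomes, g, sensors, bands,
                              p$measure, n_boot = 2000, seed = 11)
    df <- tc$curve
    df$group <- g; df$region <- p$region; df$measure <- p$measure
    rows[[length(rows) + 1]] <- df
  }
  cat(sprintf("%s %s [%s]:\n", p$measure, p$region, p$bands))
  sub <- do.call(rbind, rows[(length(rows) - 2):length(rows)])
  print(sub[, c("group", "age", "mean", "ci_low", "ci_high")],
        row.names = FALSE)
}
write.csv(do.call(rbind, rows), file.path(out_dir, "trajectories.csv"),
          row.names = FALSE)
cat("Trajectories written to", file.path(out_dir, "trajectories.csv"), "\n")
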