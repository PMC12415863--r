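#!/usr/bin/env Rscript
# Step 3 -- fit all endpoint models on the simulated datasets.
#
# For every species and endpoint this reproduces the modeling protocol:
# stratified 18/12 train/test split, min-max normalization fitted on the
# training split, and a trial-and-error architecture search over hidden sizes
# 4-10, three hidden transfer functions and three training algorithms, scored
# by held-out conventional R^2. Writes the Table-7-style performance report
# and the full per-endpoint leaderboards.

suppressPackageStartupMessages(library(anesdose))

cfg <- read_run_config(if (file.exists("analysis/run_config.yaml"))
  "analysis/run_config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
board_dir <- file.path(cfg$output_dir, "leaderboards")
dir.create(board_dir, recursive = TRUE, showWarnings = FALSE)

endpoints <- c("IT", "RT", "WBC", "RBC", "HGB", "HCT")
fits <- list()
for (sp in cfg$species) {
  path <- file.path(data_dir, paste0(sp, ".csv"))
  if (!file.exists(path)) stop("run analysis/01_simulate.R first: ", path)
  d <- read_records(path)
  split <- split_dataset(d, seed = cfg$seed)
  for (ep in endpoints) {
    s <- architecture_search(split$train, split$test, ep, seed = cfg$seed)
    fits[[paste(sp, ep)]] <- s$best
    write.csv(s$leaderboard,
              file.path(board_dir, sprintf("%s_%s.csv", sp, ep)),
              row.names = FALSE)
    te <- s$best$rows[s$best$rows$phase == "testing", ]
    message(sprintf(
      "[fit] %s %s: best %s %s/%s  testing R2 %.4f, MAPE %.2f%% (%s)",
      sp, ep, te$architecture, te$hidden_activation, te$trainer,
      te$r2_conventional, te$mape, te$mape_band))
  }
}

report <- performance_report(fits)
write.csv(report, file.path(cfg$output_dir, "performance_report.csv"),
          row.names = FALSE)
writeLines(format_performance_report(report),
           file.path(cfg$output_dir, "performance_report.txt"))
message(sprintf("[fit] %d report rows -> %s", nrow(report),
                file.path(cfg$output_dir, "performance_report.csv")))
message(paste(format_performance_report(report), collapse = "\n"))
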