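#!/usr/bin/env Rscript
# Step 4 -- welfare-limited dose recommendation per species.
#
# Using the fitted induction-time and recovery-time models, scan each species'
# tested concentration range at 1 uL/L resolution and report the lowest dose
# whose predicted IT is at most 180 s and predicted RT at most 300 s (the
# acceptability thresholds for a usable anesthetic dose).

suppressPackageStartupMessages(library(anesdose))

cfg <- read_run_config(if (file.exists("analysis/run_config.yaml"))
  "analysis/run_config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
ranges <- list(common_carp = c(800, 1400), danube_sturgeon = c(500, 1000),
               rainbow_trout = c(400, 800))

recs <- do.call(rbind, lapply(cfg$species, function(sp) {
  path <- file.path(data_dir, paste0(sp, ".csv"))
  if (!file.exists(path)) stop("run analysis/01_simulate.R first: ", path)
  d <- read_records(path)
  split <- split_dataset(d, seed = cfg$seed)
  fit_it <- architecture_search(split$train, split$test, "IT",
                                seed = cfg$seed)$best
  fit_rt <- architecture_search(split$train, split$test, "RT",
                                seed = cfg$seed)$best
  rec <- recommend_dose(fit_it, fit_rt, ranges[[sp]], step = 1,
                        it_max = cfg$it_max_s, rt_max = cfg$rt_max_s)
  message(sprintf(
    "[dose] %s: %g uL/L  (predicted IT %.1f s <= %g, RT %.1f s <= %g: %s)",
    sp, rec$concentration, rec$predicted_IT, cfg$it_max_s, rec$predicted_RT,
    cfg$rt_max_s, rec$constraints_met))
  data.frame(species = sp, concentration_uL_per_L = rec$concentration,
             predicted_IT_s = rec$predicted_IT,
             predicted_RT_s = rec$predicted_RT,
             constraints_met = rec$constraints_met)
}))

dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
write.csv(recs, file.path(cfg$output_dir, "dose_recommendations.csv"),
          row.names = FALSE)
message(sprintf("[dose] wrote %s",
                file.path(cfg$output_dir, "dose_recommendations.csv")))
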