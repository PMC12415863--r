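#!/usr/bin/env Rscript
# Step 1 -- simulate per-fish anesthesia datasets for all three species.
#
# Each dataset emulates the experimental design the models assume: 10 fish at
# each of the three nutmeg-oil concentrations tested per species, with six
# endpoints per fish (IT, RT, WBC, RBC, HGB, HCT) drawn around the generative
# dose-response curves with 3% multiplicative lognormal noise. Outputs one CSV
# per species under results/data/.

suppressPackageStartupMessages(library(anesdose))

cfg <- read_run_config(if (file.exists("analysis/run_config.yaml"))
  "analysis/run_config.yaml")
out_dir <- file.path(cfg$output_dir, "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message(sprintf("[simulate] seed %d, noise CV %g, %d fish/dose",
                cfg$seed, cfg$noise_cv, cfg$n_per_dose))
for (sp in cfg$species) {
  prof <- make_profile(sp, n_per_dose = cfg$n_per_dose,
                       noise_cv = cfg$noise_cv, seed = cfg$seed)
  d <- generate_dataset(prof)
  path <- file.path(out_dir, paste0(sp, ".csv"))
  write_records(d, path)
  it_range <- tapply(d$IT_s, d$concentration_uL_per_L, mean)
  message(sprintf(
    "[simulate] %s: %d records at %s uL/L; mean IT %s s -> wrote %s",
    sp, nrow(d), paste(prof$concentrations, collapse = "/"),
    paste(sprintf("%.0f", it_range), collapse = "/"), path))
}
message("[simulate] done")
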