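#!/usr/bin/env Rscript
# Step 2 -- audit the packaged zoo of 18 published trained networks and tabulate
# their predictions at the tested doses.
#
# The zoo is a digit-for-digit transcription of the printed weight tables;
# this step runs the validation checks (architecture agreement, finiteness,
# row contiguity) on every entry, collects the transcription caveats, and
# evaluates each network across its species' tested dose range. Because the
# printed tables never resolve their input scale, predictions are tagged
# "unverified" and reported for the raw uL/L convention.

suppressPackageStartupMessages(library(anesdose))

cfg <- read_run_config(if (file.exists("analysis/run_config.yaml"))
  "analysis/run_config.yaml")
dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

zoo <- load_zoo()
message(sprintf("[zoo] loaded %d published networks", length(zoo)))

validation <- do.call(rbind, lapply(zoo, function(e) {
  v <- validate_entry(e)
  data.frame(species = v$species, endpoint = v$endpoint,
             architecture = e$architecture,
             hidden_activation = e$params$hidden_activation,
             trainer = e$trainer_name,
             all_pass = v$all_pass,
             failed_checks = paste(v$checks$check[!v$checks$pass],
                                   collapse = "; "),
             caveats = paste(v$caveats, collapse = " | "))
}))
write.csv(validation, file.path(cfg$output_dir, "zoo_validation.csv"),
          row.names = FALSE)
flagged <- validation[!validation$all_pass, ]
message(sprintf("[zoo] %d/18 entries pass all checks; %d carry printed inconsistencies:",
                sum(validation$all_pass), nrow(flagged)))
for (k in seq_len(nrow(flagged))) {
  message(sprintf("[zoo]   %s %s: %s", flagged$species[k],
                  flagged$endpoint[k], flagged$caveats[k]))
}

doses <- list(common_carp = c(800, 1200, 1400),
              danube_sturgeon = c(500, 750, 1000),
              rainbow_trout = c(400, 600, 800))
preds <- do.call(rbind, lapply(zoo, function(e) {
  cs <- doses[[e$species]]
  p <- zoo_predict(e$species, e$endpoint, cs, zoo = zoo)
  data.frame(species = e$species, endpoint = e$endpoint,
             concentration_uL_per_L = cs, prediction = p$value,
             input_scale = p$input_scale)
}))
write.csv(preds, file.path(cfg$output_dir, "zoo_predictions.csv"),
          row.names = FALSE)
message(sprintf("[zoo] wrote %s and %s",
                file.path(cfg$output_dir, "zoo_validation.csv"),
                file.path(cfg$output_dir, "zoo_predictions.csv")))
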