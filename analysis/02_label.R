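#!/usr/bin/env Rscript
# Label every meal: 2-h incremental AUC above the pre-meal anchor, expanding
# personal baseline, binary excursion label, usability; then apply the
# cohort eligibility filter (>= 20 usable observations, both classes
# present). Writes observations.csv and exclusions.csv.

library(ppgv)

cohort_dir <- "results/cohort"
dirs <- list.dirs(cohort_dir, recursive = FALSE)
stopifnot(length(dirs) > 0)
cohort <- lapply(dirs, read_canonical)

obs <- do.call(rbind, lapply(cohort, label_participant))
el <- apply_eligibility(obs, min_obs = 20)

out_obs <- obs
out_obs$meal_time <- format(out_obs$meal_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
write.csv(out_obs, "results/observations.csv", row.names = FALSE)
write.csv(el$exclusions, "results/exclusions.csv", row.names = FALSE)

usable <- table(el$observations$participant_id)
message(sprintf("%d of %d participants eligible (%s)",
                length(el$included), length(cohort),
                paste(sprintf("%s: %d", names(table(el$exclusions$reason)),
                              table(el$exclusions$reason)), collapse = ", ")))
message(sprintf("usable observations per person: mean %.2f (SD %.2f)",
                mean(usable), sd(usable)))
message(sprintf("excursion rate among usable observations: %.2f%%",
                100 * mean(el$observations$label)))
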