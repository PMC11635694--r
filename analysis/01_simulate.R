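#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-condition cohort and record its
# design and planted ground truth.

source("analysis/00_config.R")

sim <- study_cohort()
cfg <- study_config()
man <- sim$cohort$manifest

cat(sprintf("Simulated %d subjects x %d conditions = %d runs (%d frames @ TR %gs)\n",
            cfg$n_subjects, length(unique(man$condition)), nrow(man),
            cfg$n_frames, cfg$tr_seconds))
cat(sprintf("Age %.1f +- %.1f years; sex %d M / %d F\n",
            mean(man$age), sd(man$age),
            sum(man$sex[!duplicated(man$subject)] == "M"),
            sum(man$sex[!duplicated(man$subject)] == "F")))

write_tsv(man, "manifest.tsv")

occ <- do.call(rbind, lapply(names(sim$truth$expected_dwell), function(cond)
  data.frame(condition = cond, state = cfg$state_names,
             stationary_occupancy = sim$truth$expected_dwell[[cond]])))
write_tsv(occ, "expected_occupancy.tsv")

cat("\nPlanted stationary occupancy (expected fraction of scan time):\n")
print(reshape(occ, idvar = "state", timevar = "condition", direction = "wide"),
      row.names = FALSE)
cat("\nUnder MPH the DMN and DAN states gain occupancy and the FPN state",
    "loses it;\nunder HAL the SM-DMN state gains. These are the effects the",
    "later stages\nshould recover from the signals alone.\n")
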