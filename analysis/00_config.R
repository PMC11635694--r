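# Shared configuration for the analysis workflow. Every stage re-simulates
# the cohort deterministically from this config (generation takes seconds),
# so no intermediate volumes need to be stored; stage outputs are small
# summary tables under results/.

library(capdyn)

STUDY_SEED <- 1L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Default study conditions: 59 subjects x 3 conditions (PBO, MPH, HAL),
# 235 frames at TR = 2 s, 129 ROIs (first 53 cortical), 300 striatal
# voxels, planted MPH effects on DMN/DAN/FPN dynamics and on striatal
# weight rankings, with per-subject coupling between the two.
study_config <- function() {
  simulation_config(coupling = TRUE, seed = STUDY_SEED)
}

study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(study_config())
    cache
  }
})

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
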