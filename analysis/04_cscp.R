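#!/usr/bin/env Rscript
# Stage 4: corticostriatal configuration profiles; AD / ROR / ES subject
# scores against the within-session placebo null, and voxelwise
# localization of the MPH ROR effect.

source("analysis/00_config.R")

sim <- study_cohort()
cohort <- sim$cohort

all_scores <- list()
for (metric in c("AD", "ROR", "ES")) {
  cs <- cohort_cscp(cohort, metric)
  all_scores[[metric]] <- cs$scores
  if (metric == "ROR") ror <- cs
}
scores <- do.call(rbind, all_scores)
write_tsv(scores, "cscp_scores.tsv")

cat("Subject-wise mean scores by condition pair:\n")
agg <- aggregate(score ~ metric + condition_pair, scores, mean)
print(reshape(agg, idvar = "metric", timevar = "condition_pair",
              direction = "wide"), row.names = FALSE, digits = 4)

for (metric in c("AD", "ROR", "ES")) {
  sc <- all_scores[[metric]]
  a <- rm_anova(transform(sc, condition = condition_pair), "score", "condition")
  row <- a[a$effect == "condition", ]
  cat(sprintf("%s condition ANOVA: F(%g, %.0f) = %.2f, p = %.2g\n",
              metric, row$df1, row$df2, row$F, row$p))
}

pair_score <- function(sc, pr) {
  x <- sc[sc$condition_pair == pr, ]
  x$score[order(x$subject)]
}
sc <- all_scores$ROR
posthoc <- rbind(
  cbind(contrast = "MPH-PBO vs split",
        paired_t(pair_score(sc, "MPH-PBO"), pair_score(sc, "PBO-split"), 3L)),
  cbind(contrast = "HAL-PBO vs split",
        paired_t(pair_score(sc, "HAL-PBO"), pair_score(sc, "PBO-split"), 3L)),
  cbind(contrast = "MPH-PBO vs HAL-PBO",
        paired_t(pair_score(sc, "MPH-PBO"), pair_score(sc, "HAL-PBO"), 3L)))
write_tsv(posthoc, "cscp_posthoc.tsv")
cat("\nROR post hoc contrasts (the planted permutations act under MPH only):\n")
print(posthoc[, c("contrast", "t", "p_corrected", "d")], row.names = FALSE,
      digits = 3)

nodes <- voxelwise_paired_test(ror$maps[["MPH-PBO"]], ror$maps[["PBO-split"]],
                               p_threshold = 0.001, min_extent = 10)
cat(sprintf("\nVoxelwise paired test: %d striatal node(s) above threshold\n",
            length(nodes$nodes)))
if (length(nodes$nodes)) {
  node_tab <- do.call(rbind, lapply(seq_along(nodes$nodes), function(i)
    data.frame(node = i, size = nodes$nodes[[i]]$size,
               peak_t = nodes$nodes[[i]]$peak_t)))
  write_tsv(node_tab, "nodes.tsv")
  coords <- do.call(rbind, lapply(seq_along(nodes$nodes), function(i)
    data.frame(node = i, i = nodes$nodes[[i]]$coords[, 1],
               j = nodes$nodes[[i]]$coords[, 2],
               k = nodes$nodes[[i]]$coords[, 3])))
  write_tsv(coords, "node_voxels.tsv")
}
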