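# End-to-end study replica on a synthetic cohort: simulate -> assign
# frames -> dwell metrics and ANOVAs -> anticorrelation mixed model ->
# CSCP metrics and localization -> dynamics x reconfiguration linkage.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Deterministic given the config seed. Stages: (1) cohort simulation;
#' (2) frame assignment and dwell metrics, drug x state interaction ANOVA,
#' per-state drug ANOVAs at alpha/8, post hoc paired t-tests at alpha/2;
#' (3) DMN-DAN beta-series anticorrelation, its ANOVA and mixed model;
#' (4) CSCP metric (default ROR) maps for MPH-PBO, HAL-PBO and the
#' placebo split-half null, subject scores, condition ANOVA, post hocs,
#' voxelwise localization; (5) time-change scores, dynamics-CSCP
#' correlation, three-way comparison, node x state table.
#'
#' @param config a [simulation_config()] with `timeseries = TRUE`.
#' @param metric CSCP metric for stages 4-5 (default `"ROR"`).
#' @param alpha family-wise alpha (default 0.05).
#' @param p_threshold,min_extent voxelwise localization settings.
#' @param out_dir optional directory; when given, stage tables are written
#'   as TSV and a JSON results manifest is emitted.
#' @return nested list of stage results.
#' @export
run_study <- function(config = simulation_config(), metric = "ROR",
                      alpha = 0.05, p_threshold = 0.001, min_extent = 10L,
                      out_dir = NULL) {
  if (!config$timeseries) stopf("run_study needs a config with timeseries = TRUE")
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  centroids <- cohort$centroids

  ## -- temporal dynamics ------------------------------------------------
  dwell <- cohort_dwell_table(cohort, centroids)
  interaction <- rm_anova(dwell, "total_time_s", c("condition", "state_name"),
                          covariates = c("age", "sex"))
  states <- centroids$state_names
  per_state <- do.call(rbind, lapply(states, function(st) {
    a <- rm_anova(dwell[dwell$state_name == st, ], "total_time_s", "condition",
                  covariates = c("age", "sex"))
    cbind(state_name = st, a[a$effect == "condition", ])
  }))
  per_state$p_corrected <- pmin(1, per_state$p * length(states))
  sig_states <- per_state$state_name[per_state$p < bonferroni_alpha(alpha, length(states))]

  wide <- function(measure, cond) {
    d <- dwell[dwell$condition == cond, ]
    m <- reshape_states(d, measure)
    m[order(rownames(m)), , drop = FALSE]
  }
  posthoc <- list()
  for (st in states) {
    for (drug in c("MPH", "HAL")) {
      tt <- paired_t(wide("total_time_s", drug)[, st],
                     wide("total_time_s", "PBO")[, st], m_comparisons = 2L)
      posthoc[[length(posthoc) + 1L]] <- cbind(
        state_name = st, contrast = paste0(drug, "-PBO"), tt)
    }
  }
  posthoc <- do.call(rbind, posthoc)

  ## -- anticorrelation --------------------------------------------------
  anti <- cohort_anticorrelation(cohort, centroids)
  anti_anova <- rm_anova(anti, "anticorr_z", "condition",
                         covariates = c("age", "sex"))
  dmn_dan_time <- rowsum(
    dwell$total_time_s[dwell$state_name %in% c("DMN", "DAN")],
    paste0(dwell$subject, "_", dwell$condition)[dwell$state_name %in% c("DMN", "DAN")])
  anti$time_in_state <- dmn_dan_time[paste0(anti$subject, "_", anti$condition), 1L]
  anti$drug <- anti$condition
  lmm <- lmm_anticorr(anti)

  ## -- CSCP -------------------------------------------------------------
  cscp <- cohort_cscp(cohort, metric)
  sc <- cscp$scores
  cscp_anova <- rm_anova(transform(sc, condition = condition_pair),
                         "score", "condition")
  pair_score <- function(pr) {
    x <- sc[sc$condition_pair == pr, ]
    x$score[order(x$subject)]
  }
  cscp_posthoc <- rbind(
    cbind(contrast = "MPH-PBO vs split",
          paired_t(pair_score("MPH-PBO"), pair_score("PBO-split"), 3L)),
    cbind(contrast = "HAL-PBO vs split",
          paired_t(pair_score("HAL-PBO"), pair_score("PBO-split"), 3L)),
    cbind(contrast = "MPH-PBO vs HAL-PBO",
          paired_t(pair_score("MPH-PBO"), pair_score("HAL-PBO"), 3L)))
  nodes <- voxelwise_paired_test(cscp$maps[["MPH-PBO"]], cscp$maps[["PBO-split"]],
                                 p_threshold, min_extent)

  ## -- linkage ----------------------------------------------------------
  sig <- if (length(sig_states)) sig_states else config$sig_states
  nonsig <- setdiff(states, sig)
  subj <- sort(unique(dwell$subject))
  x <- sc$score[sc$condition_pair == "MPH-PBO"][order(sc$subject[sc$condition_pair == "MPH-PBO"])]
  y_all <- cohort_time_change_scores(dwell, states = NULL, normalize = TRUE)
  y_sig <- cohort_time_change_scores(dwell, states = sig, normalize = TRUE)
  y_nonsig <- if (length(nonsig))
    cohort_time_change_scores(dwell, states = nonsig, normalize = TRUE) else NULL
  stopifnot(identical(y_all$subject, subj))
  link_all <- dynamics_cscp_correlation(y_all$score, x)
  comparison <- if (!is.null(y_nonsig))
    three_way_comparison(x, y_all$score, y_sig$score, y_nonsig$score) else NULL

  node_table <- NULL
  if (length(nodes$nodes) && length(sig)) {
    node_scores <- as.data.frame(lapply(seq_along(nodes$nodes), function(i) {
      vapply(subj, function(s)
        subject_cscp_score(cscp$maps[["MPH-PBO"]][[s]], nodes$nodes[[i]]$coords),
        numeric(1L))
    }))
    names(node_scores) <- paste0("node", seq_along(nodes$nodes))
    state_changes <- as.data.frame(lapply(sig, function(st) {
      vapply(subj, function(s) {
        d <- dwell[dwell$subject == s & dwell$state_name == st, ]
        abs(d$total_time_s[d$condition == "MPH"] - d$total_time_s[d$condition == "PBO"])
      }, numeric(1L))
    }))
    names(state_changes) <- sig
    node_table <- node_level_analysis(node_scores, state_changes)
  }

  res <- list(config = config, truth = sim$truth, dwell = dwell,
              interaction = interaction, per_state = per_state,
              sig_states = sig_states, posthoc = posthoc,
              anticorrelation = anti, anticorr_anova = anti_anova,
              lmm = lmm[c("fixed", "varcomp", "marginal_r2", "conditional_r2")],
              cscp_scores = sc, cscp_anova = cscp_anova,
              cscp_posthoc = cscp_posthoc, nodes = nodes,
              linkage = list(correlation = link_all, comparison = comparison,
                             node_table = node_table))
  if (!is.null(out_dir)) write_study_results(res, out_dir)
  res
}

reshape_states <- function(d, measure) {
  m <- tapply(d[[measure]], list(d$subject, d$state_name), mean)
  m[, unique(d$state_name), drop = FALSE]
}

write_study_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res$dwell, "dwell.tsv")
  wt(res$interaction, "anova_interaction.tsv")
  wt(res$per_state, "anova_per_state.tsv")
  wt(res$posthoc, "posthoc.tsv")
  wt(res$anticorrelation, "anticorrelation.tsv")
  wt(res$cscp_scores, "cscp_scores.tsv")
  wt(res$cscp_posthoc, "cscp_posthoc.tsv")
  if (!is.null(res$linkage$comparison)) wt(res$linkage$comparison, "comparison.tsv")
  if (!is.null(res$linkage$node_table)) wt(res$linkage$node_table, "node_level.tsv")
  manifest <- list(
    seed = res$config$seed, n_subjects = res$config$n_subjects,
    sig_states = res$sig_states,
    interaction_p = res$interaction$p[grepl(":", res$interaction$effect)],
    linkage_r = res$linkage$correlation$r,
    linkage_p = res$linkage$correlation$p,
    n_nodes = length(res$nodes$nodes))
  jsonlite::write_json(manifest, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
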