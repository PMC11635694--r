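# Ties between drug-induced change in network temporal dynamics and
# corticostriatal reconfiguration: the absolute time-change score, its
# correlation with CSCP scores, the three-way dependent-correlation
# comparison, and node x state localization.

#' Absolute change in time spent in states
#'
#' Sum over a state subset of |total time under drug - total time under
#' placebo|, optionally divided by the number of states summed (the
#' normalization used when comparing subsets of different size).
#'
#' @param dwell_drug,dwell_pbo [dwell_metrics()] tables for the same
#'   subject under drug and placebo.
#' @param states state subset: indices or state names (default all).
#' @param normalize divide by the number of states summed.
#' @return scalar score in seconds.
#' @export
abs_time_change_score <- function(dwell_drug, dwell_pbo, states = NULL,
                                  normalize = FALSE) {
  if (nrow(dwell_drug) != nrow(dwell_pbo))
    stopf("dwell tables have different state spaces")
  if (is.null(states)) states <- dwell_drug$state
  if (is.character(states)) states <- match(states, dwell_drug$state_name)
  if (length(states) == 0L || anyNA(states)) stopf("empty or unknown state subset")
  delta <- dwell_drug$total_time_s[states] - dwell_pbo$total_time_s[states]
  s <- sum(abs(delta))
  if (normalize) s <- s / length(states)
  s
}

#' Per-subject time-change scores from a long dwell table
#'
#' @param dwell long dwell table from [cohort_dwell_table()].
#' @param drug,placebo condition labels to contrast.
#' @param states state subset (names or indices), default all.
#' @param normalize divide by number of states summed.
#' @return data.frame (subject, score).
#' @export
cohort_time_change_scores <- function(dwell, drug = "MPH", placebo = "PBO",
                                      states = NULL, normalize = FALSE) {
  subjects <- unique(dwell$subject)
  score <- vapply(subjects, function(s) {
    dd <- dwell[dwell$subject == s & dwell$condition == drug, ]
    dp <- dwell[dwell$subject == s & dwell$condition == placebo, ]
    dd <- dd[order(dd$state), ]; dp <- dp[order(dp$state), ]
    abs_time_change_score(dd, dp, states, normalize)
  }, numeric(1L))
  data.frame(subject = subjects, score = score, stringsAsFactors = FALSE)
}

#' Correlation between dynamics change and CSCP score
#'
#' @param scores per-subject time-change scores.
#' @param cscp_scores per-subject CSCP scores, aligned by position.
#' @return data.frame (r, p, n) from a two-sided Pearson test.
#' @export
dynamics_cscp_correlation <- function(scores, cscp_scores) {
  if (length(scores) != length(cscp_scores)) stopf("score vectors differ in length")
  if (length(scores) < 4L) stopf("need n >= 4")
  if (stats::sd(scores) == 0 || stats::sd(cscp_scores) == 0)
    stopf("degenerate input: zero variance")
  ct <- stats::cor.test(scores, cscp_scores)
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Three-way dependent-correlation comparison
#'
#' With x the CSCP score and y varying over time-change in all states,
#' significant states, and non-significant states, compares
#' r(x, y_all) against r(x, y_nonsig) and against r(x, y_sig) with
#' Steiger's z for overlapping dependent correlations.
#'
#' @param cscp_scores per-subject CSCP scores (shared x).
#' @param score_all,score_sig,score_nonsig per-subject time-change scores.
#' @param sided sidedness of the Steiger tests (default one-sided).
#' @return data.frame, one row per comparison: comparison, r_all, r_other,
#'   r_y1y2, n, z, p.
#' @export
three_way_comparison <- function(cscp_scores, score_all, score_sig,
                                 score_nonsig, sided = "one") {
  n <- length(cscp_scores)
  r_all <- stats::cor(cscp_scores, score_all)
  r_sig <- stats::cor(cscp_scores, score_sig)
  r_nonsig <- stats::cor(cscp_scores, score_nonsig)
  cmp <- function(r_other, r_yy, name) {
    st <- steiger_z(r_all, r_other, r_yy, n, sided)
    data.frame(comparison = name, r_all = r_all, r_other = r_other,
               r_y1y2 = r_yy, n = n, z = st$z, p = st$p,
               stringsAsFactors = FALSE)
  }
  rbind(cmp(r_nonsig, stats::cor(score_all, score_nonsig), "all_vs_nonsig"),
        cmp(r_sig, stats::cor(score_all, score_sig), "all_vs_sig"))
}

#' Node x state correlation table with joint Bonferroni correction
#'
#' One Pearson test per (striatal node, state) pair between node-wise CSCP
#' scores and per-state time change; corrected p multiplies the raw
#' two-sided p by the full table size (n_nodes x n_states).
#'
#' @param node_scores data.frame/matrix, subjects x nodes.
#' @param state_changes data.frame/matrix, subjects x states (signed or
#'   absolute change in time per state).
#' @return data.frame: node, state, r, p, p_corrected, one row per pair.
#' @export
node_level_analysis <- function(node_scores, state_changes) {
  node_scores <- as.data.frame(node_scores)
  state_changes <- as.data.frame(state_changes)
  if (ncol(node_scores) == 0L || ncol(state_changes) == 0L)
    stopf("node and state lists must be nonempty")
  m <- ncol(node_scores) * ncol(state_changes)
  rows <- list()
  for (nd in names(node_scores)) {
    for (st in names(state_changes)) {
      ct <- stats::cor.test(node_scores[[nd]], state_changes[[st]])
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, state = st, r = unname(ct$estimate), p = ct$p.value,
        p_corrected = min(1, ct$p.value * m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
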