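# Frame-state assignment and dwell metrics: each fMRI frame is labelled
# with the transient network state whose centroid it most resembles, and
# per-state occupancy is summarized as total time, transitions (entries),
# and persistence (mean visit duration).

#' Assign each frame to its nearest CAP state
#'
#' Each ROI column is z-scored across time, then frame `t` is labelled with
#' the state whose centroid has the highest Pearson spatial correlation
#' with the frame's ROI vector. Ties break toward the lowest state index.
#' Zero-variance frames (after normalization) cannot be correlated; they
#' are assigned by the tie-break rule (state 1) with a warning.
#'
#' @param ts a [roi_timeseries()].
#' @param centroids a [centroid_set()] with matching ROI count.
#' @param method `"correlation"` (default) or `"euclidean"` distance on the
#'   z-scored frames.
#' @return list of class `state_labels`: `labels` (integer per frame),
#'   `tr_seconds`, `n_states`, `state_names`.
#' @export
assign_frames <- function(ts, centroids, method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  X <- ts$values
  C <- centroids$values
  if (ncol(X) != ncol(C))
    stopf("time series has %d ROIs but centroids have %d", ncol(X), ncol(C))
  # z-score each ROI across time; constant columns become 0
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  if (method == "correlation") {
    Xc <- X - rowMeans(X)
    Cc <- C - rowMeans(C)
    xn <- sqrt(rowSums(Xc^2))
    cn <- sqrt(rowSums(Cc^2))
    flat <- xn == 0
    xn[flat] <- 1
    S <- (Xc %*% t(Cc)) / (xn %o% cn)
    if (any(flat)) {
      warnf("%d zero-variance frame(s) assigned by tie-break rule", sum(flat))
      S[flat, ] <- 0
    }
  } else {
    S <- -outer(rowSums(X^2), rep(1, nrow(C))) +
      2 * X %*% t(C) - outer(rep(1, nrow(X)), rowSums(C^2))
  }
  labels <- max.col(S, ties.method = "first")
  structure(list(labels = labels, tr_seconds = ts$tr_seconds,
                 n_states = nrow(C), state_names = centroids$state_names),
            class = "state_labels")
}

as_state_labels <- function(labels, tr_seconds = 2, n_states = max(labels),
                            state_names = default_state_names(n_states)) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stopf("label sequence must be nonempty")
  if (any(labels < 1L | labels > n_states)) stopf("label out of range 1..%d", n_states)
  structure(list(labels = labels, tr_seconds = tr_seconds,
                 n_states = as.integer(n_states), state_names = state_names),
            class = "state_labels")
}

#' Dwell metrics per state: total time, transitions, persistence
#'
#' For each state: total time is frames-in-state times TR; transitions is
#' the number of maximal runs of the state (a run starting at frame 1
#' counts as an entry); persistence is the mean run length times TR, `NA`
#' when the state is never visited. By construction
#' `total_time = transitions * persistence` exactly for every visited
#' state, and total times sum to scan duration.
#'
#' @param labels a `state_labels` object (from [assign_frames()] or
#'   [as_state_labels()]), or a bare integer vector.
#' @param tr_seconds,n_states used only when `labels` is a bare vector.
#' @return data.frame with one row per state: `state`, `state_name`,
#'   `total_time_s`, `transitions`, `persistence_s`.
#' @export
dwell_metrics <- function(labels, tr_seconds = 2, n_states = NULL) {
  if (!inherits(labels, "state_labels"))
    labels <- as_state_labels(labels, tr_seconds,
                              if (is.null(n_states)) max(labels) else n_states)
  tr <- labels$tr_seconds
  k <- labels$n_states
  r <- rle(labels$labels)
  total <- transitions <- numeric(k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    total[s] <- sum(runs) * tr
    transitions[s] <- length(runs)
  }
  persistence <- ifelse(transitions > 0, total / transitions, NA_real_)
  data.frame(state = seq_len(k),
             state_name = labels$state_names[seq_len(k)],
             total_time_s = total, transitions = transitions,
             persistence_s = persistence, stringsAsFactors = FALSE)
}

#' Long-format dwell table for a cohort
#'
#' Runs frame assignment and [dwell_metrics()] for every run in a cohort,
#' returning (subject, condition, state, total_time_s, transitions,
#' persistence_s) rows.
#'
#' @param cohort cohort list with `manifest` and `roi_ts` (see
#'   [simulate_cohort()]); if `roi_ts` is empty, `label_sequences` must
#'   supply per-run label vectors keyed `"<subject>_<condition>"`.
#' @param centroids a [centroid_set()]; required when assigning from ROI
#'   series.
#' @param label_sequences optional named list of precomputed label vectors.
#' @param tr_seconds repetition time used with `label_sequences`.
#' @return long-format data.frame including manifest covariates.
#' @export
cohort_dwell_table <- function(cohort, centroids = NULL,
                               label_sequences = NULL, tr_seconds = 2) {
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    key <- paste0(man$subject[i], "_", man$condition[i])
    if (!is.null(label_sequences)) {
      labs <- as_state_labels(label_sequences[[key]], tr_seconds)
      if (!is.null(centroids)) labs$n_states <- nrow(centroids$values)
    } else {
      labs <- assign_frames(cohort$roi_ts[[key]], centroids)
    }
    dm <- dwell_metrics(labs)
    dm$subject <- man$subject[i]; dm$condition <- man$condition[i]
    dm$age <- man$age[i]; dm$sex <- man$sex[i]
    out[[i]] <- dm
  }
  do.call(rbind, out)
}

#' Per-frame network beta series
#'
#' For each frame, the ordinary-least-squares slope (with intercept) of the
#' frame's ROI vector on one state map; used to obtain DMN and DAN
#' activity time courses, one map at a time.
#'
#' @param ts a [roi_timeseries()].
#' @param state_map numeric vector (one centroid row) with nonzero
#'   variance.
#' @return numeric vector of per-frame slopes.
#' @export
network_beta_series <- function(ts, state_map) {
  state_map <- as.numeric(state_map)
  if (length(state_map) != ncol(ts$values))
    stopf("state map length %d != ROI count %d", length(state_map), ncol(ts$values))
  mc <- state_map - mean(state_map)
  denom <- sum(mc^2)
  if (denom == 0) stopf("state map has zero variance")
  as.numeric((ts$values - rowMeans(ts$values)) %*% mc) / denom
}

#' Fisher-z anticorrelation between two network time courses
#'
#' `atanh` of the Pearson correlation between two beta series; negative
#' values indicate anticorrelation.
#'
#' @param beta_a,beta_b numeric series of equal length >= 3.
#' @return Fisher z value.
#' @export
anticorrelation_z <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b)) stopf("series lengths differ")
  if (length(beta_a) < 3L) stopf("need >= 3 frames")
  if (stats::sd(beta_a) == 0 || stats::sd(beta_b) == 0)
    stopf("degenerate input: a series has zero variance; add noise or check extraction")
  r <- stats::cor(beta_a, beta_b)
  if (abs(r) >= 1 - 1e-12)
    stopf("degenerate input: |r| = 1; Fisher z undefined")
  atanh(r)
}

#' DMN-DAN anticorrelation per cohort run
#'
#' Convenience wrapper: for every run, regress frames on the DMN and DAN
#' centroid maps and Fisher-z the correlation between the two beta series.
#'
#' @param cohort cohort list with `manifest` and `roi_ts`.
#' @param centroids a [centroid_set()] containing states named in
#'   `networks`.
#' @param networks two state names (default DMN, DAN).
#' @return data.frame (subject, condition, age, sex, anticorr_z).
#' @export
cohort_anticorrelation <- function(cohort, centroids,
                                   networks = c("DMN", "DAN")) {
  idx <- match(networks, centroids$state_names)
  if (anyNA(idx)) stopf("states %s not in centroid set",
                        paste(networks[is.na(idx)], collapse = ", "))
  man <- cohort$manifest
  z <- numeric(nrow(man))
  for (i in seq_len(nrow(man))) {
    key <- paste0(man$subject[i], "_", man$condition[i])
    ts <- cohort$roi_ts[[key]]
    ba <- network_beta_series(ts, centroids$values[idx[1L], ])
    bb <- network_beta_series(ts, centroids$values[idx[2L], ])
    z[i] <- anticorrelation_z(ba, bb)
  }
  cbind(man, anticorr_z = z)
}
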