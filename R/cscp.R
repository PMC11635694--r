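# Corticostriatal configuration profiles (CSCPs): per striatal voxel, the
# vector of Fisher-z connectivity with each cortical ROI, and three
# divergence metrics between condition pairs -- aggregate divergence (AD),
# rank-order rearrangement (ROR), entropy shift (ES) -- plus the
# within-session placebo split-half null and voxelwise localization.

#' Corticostriatal connectivity profile
#'
#' Fisher-z transformed Pearson correlation between each striatal voxel
#' time course and each cortical ROI time course. `r` is clipped to
#' `|r| <= 1 - 1e-7` before `atanh` so noiseless constructions stay
#' finite. Zero-variance voxel or ROI columns are flagged, their entries
#' set to `NA`, and excluded downstream.
#'
#' @param striatal a [voxel_timeseries()].
#' @param cortical a [roi_timeseries()] of cortical ROI means.
#' @param condition optional condition label carried in the result.
#' @return list of class `profile_matrix`: `z` (voxels x ROIs),
#'   `voxel_coords`, `roi_names`, `condition`.
#' @export
connectivity_profile <- function(striatal, cortical, condition = NA_character_) {
  if (nrow(striatal$values) != nrow(cortical$values))
    stopf("frame counts differ: %d vs %d", nrow(striatal$values), nrow(cortical$values))
  if (nrow(striatal$values) < 10L) stopf("need >= 10 frames for connectivity")
  sdv <- apply(striatal$values, 2L, stats::sd)
  sdr <- apply(cortical$values, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(striatal$values, cortical$values))
  if (any(sdv == 0) || any(sdr == 0)) {
    warnf("zero-variance columns flagged: %d voxel(s), %d ROI(s)",
          sum(sdv == 0), sum(sdr == 0))
    r[sdv == 0, ] <- NA_real_
    r[, sdr == 0] <- NA_real_
  }
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  structure(list(z = z, voxel_coords = striatal$voxel_coords,
                 roi_names = cortical$roi_names, condition = condition,
                 n_frames = nrow(striatal$values)),
            class = "profile_matrix")
}

check_profiles_match <- function(p_a, p_b) {
  if (!identical(dim(p_a$z), dim(p_b$z)))
    stopf("profile shapes differ: %s vs %s",
          paste(dim(p_a$z), collapse = "x"), paste(dim(p_b$z), collapse = "x"))
  if (!identical(p_a$roi_names, p_b$roi_names))
    stopf("profiles have different ROI orderings")
  invisible(TRUE)
}

cscp_map <- function(values, voxel_coords, metric, condition_pair = NA_character_) {
  structure(list(values = values, voxel_coords = voxel_coords,
                 metric = metric, condition_pair = condition_pair),
            class = "cscp_map")
}

#' Aggregate divergence (AD)
#'
#' Per striatal voxel, the sum over cortical ROIs of the absolute change in
#' Fisher-z connectivity between the two conditions: a measure of absolute
#' change in connectivity magnitude.
#'
#' @param p_a,p_b matched [connectivity_profile()]s (e.g. drug, placebo).
#' @return list of class `cscp_map` with per-voxel `values`.
#' @export
aggregate_divergence <- function(p_a, p_b) {
  check_profiles_match(p_a, p_b)
  cscp_map(rowSums(abs(p_a$z - p_b$z)), p_a$voxel_coords, "AD",
           paste(p_a$condition, p_b$condition, sep = "-"))
}

#' Connectivity-strength ranks of a profile
#'
#' Rank 1 = strongest (most positive z), ordinal ranking with ties broken
#' deterministically by ROI order.
#'
#' @param p a [connectivity_profile()], or a bare voxels x ROIs matrix.
#' @return integer matrix of ranks, same shape as the profile.
#' @export
profile_ranks <- function(p) {
  z <- if (inherits(p, "profile_matrix")) p$z else as.matrix(p)
  t(apply(z, 1L, function(row) rank(-row, ties.method = "first")))
}

#' Rank-order rearrangement (ROR)
#'
#' Cortical ROIs are ranked by connectivity strength at each voxel under
#' each condition; ROR is the per-voxel sum of absolute rank changes: a
#' measure of absolute change in relative connectivity. Rank-based, so
#' invariant under any strictly monotone transform of z.
#'
#' @param p_a,p_b matched [connectivity_profile()]s.
#' @return list of class `cscp_map`.
#' @export
rank_order_rearrangement <- function(p_a, p_b) {
  check_profiles_match(p_a, p_b)
  na_row <- rowSums(is.na(p_a$z)) > 0 | rowSums(is.na(p_b$z)) > 0
  ra <- profile_ranks(p_a$z)
  rb <- profile_ranks(p_b$z)
  v <- rowSums(abs(ra - rb))
  v[na_row] <- NA_real_
  cscp_map(v, p_a$voxel_coords, "ROR",
           paste(p_a$condition, p_b$condition, sep = "-"))
}

profile_entropy <- function(z, eps = 1e-12) {
  a <- abs(z) + eps
  q <- a / rowSums(a)
  -rowSums(q * log(q))
}

#' Entropy shift (ES)
#'
#' Change in the dispersion of the connectivity-strength distribution: each
#' voxel's |z| profile is normalized to probabilities
#' `q_i = (|z_i| + eps) / sum_j (|z_j| + eps)` (eps = 1e-12), Shannon
#' entropy `H = -sum q ln q` is computed per condition, and
#' `ES = |H_a - H_b|`. An all-zero profile row gets `H = ln K` via the eps
#' floor.
#'
#' @param p_a,p_b matched [connectivity_profile()]s.
#' @return list of class `cscp_map`.
#' @export
entropy_shift <- function(p_a, p_b) {
  check_profiles_match(p_a, p_b)
  cscp_map(abs(profile_entropy(p_a$z) - profile_entropy(p_b$z)),
           p_a$voxel_coords, "ES",
           paste(p_a$condition, p_b$condition, sep = "-"))
}

#' Within-session placebo split-half profiles
#'
#' Splits a run at floor(N/2) frames (first half shorter when N is odd)
#' and computes a [connectivity_profile()] on each half: the no-drug null
#' against which drug-placebo divergences are compared.
#'
#' @param striatal a [voxel_timeseries()].
#' @param cortical a matched [roi_timeseries()].
#' @return list of two `profile_matrix` objects (`first`, `second`).
#' @export
split_half_profiles <- function(striatal, cortical) {
  n <- nrow(striatal$values)
  if (n < 20L) stopf("need >= 20 frames to split, got %d", n)
  h <- n %/% 2L
  take <- function(ts, idx) {
    ts$values <- ts$values[idx, , drop = FALSE]
    ts
  }
  list(first = connectivity_profile(take(striatal, 1:h), take(cortical, 1:h),
                                    "PBO_firsthalf"),
       second = connectivity_profile(take(striatal, (h + 1L):n),
                                     take(cortical, (h + 1L):n),
                                     "PBO_secondhalf"))
}

#' Subject-wise CSCP score
#'
#' Arithmetic mean of a per-voxel metric map over the whole striatum or a
#' voxel subset (e.g. one significant node), skipping flagged (`NA`)
#' voxels.
#'
#' @param map a `cscp_map`.
#' @param voxel_subset optional matrix of (i, j, k) coordinates.
#' @return scalar mean.
#' @export
subject_cscp_score <- function(map, voxel_subset = NULL) {
  v <- map$values
  if (!is.null(voxel_subset)) {
    key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
    idx <- match(key(as.matrix(voxel_subset)), key(map$voxel_coords))
    if (anyNA(idx)) stopf("voxel subset contains coordinates not in the map")
    v <- v[idx]
  }
  if (all(is.na(v))) stopf("no defined voxels to average")
  mean(v, na.rm = TRUE)
}

#' Voxelwise paired t-test with cluster extraction
#'
#' Per-voxel paired t across subjects (one-sided, a > b); voxels below the
#' p threshold are grouped into clusters by 6-connectivity on the voxel
#' grid, clusters smaller than `min_extent` are discarded, and the
#' surviving clusters ("striatal nodes") are returned sorted by size.
#'
#' @param maps_a,maps_b lists of per-subject `cscp_map`s on the same voxel
#'   grid and subject order.
#' @param p_threshold one-sided uncorrected threshold (default 0.001).
#' @param min_extent minimum cluster size in voxels (default 10).
#' @return list of class `node_set`: `nodes` (list with `coords`, `size`,
#'   `peak_t`, `label`), `t`, `p`, `voxel_coords`.
#' @export
voxelwise_paired_test <- function(maps_a, maps_b, p_threshold = 0.001,
                                  min_extent = 10L) {
  n <- length(maps_a)
  if (n != length(maps_b)) stopf("subject counts differ")
  if (n < 3L) stopf("need >= 3 subjects for a paired test")
  A <- do.call(rbind, lapply(maps_a, `[[`, "values"))
  B <- do.call(rbind, lapply(maps_b, `[[`, "values"))
  coords <- maps_a[[1L]]$voxel_coords
  D <- A - B
  m <- colMeans(D)
  sdd <- apply(D, 2L, stats::sd)
  t <- m / (sdd / sqrt(n))
  p <- stats::pt(t, df = n - 1L, lower.tail = FALSE)  # one-sided a > b
  sig <- which(!is.na(p) & p < p_threshold)

  nodes <- list()
  if (length(sig)) {
    sc <- coords[sig, , drop = FALSE]
    comp <- cluster_6conn(sc)
    for (g in split(seq_len(nrow(sc)), comp)) {
      if (length(g) < min_extent) next
      nodes[[length(nodes) + 1L]] <- list(
        coords = sc[g, , drop = FALSE], size = length(g),
        peak_t = max(t[sig[g]]), label = "")
    }
    if (length(nodes))
      nodes <- nodes[order(vapply(nodes, `[[`, 0L, "size"), decreasing = TRUE)]
  }
  structure(list(nodes = nodes, t = t, p = p, voxel_coords = coords),
            class = "node_set")
}

# connected components under 6-connectivity (face neighbours) on integer
# voxel coordinates
cluster_6conn <- function(coords) {
  n <- nrow(coords)
  key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
  lookup <- seq_len(n)
  names(lookup) <- key
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- sweep(offs, 2L, as.numeric(coords[v, ]), "+")
      hit <- lookup[paste(nb[, 1L], nb[, 2L], nb[, 3L])]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Mean rank shifts of cortical ROIs within a striatal node
#'
#' Mean signed rank change (condition a minus condition b; negative means
#' the ROI climbed toward rank 1 under a) per cortical ROI over the node's
#' voxels; only ROIs whose mean absolute change reaches `min_shift` ranks
#' are reported, sorted by magnitude.
#'
#' @param node one element of a `node_set`'s `nodes` list (needs
#'   `coords`).
#' @param p_a,p_b matched [connectivity_profile()]s.
#' @param min_shift minimum |mean rank change| to report (default 5).
#' @return data.frame (roi, mean_rank_change).
#' @export
rank_shift_summary <- function(node, p_a, p_b, min_shift = 5) {
  check_profiles_match(p_a, p_b)
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
  idx <- match(key(node$coords), key(p_a$voxel_coords))
  if (anyNA(idx)) stopf("node voxels missing from profiles")
  ra <- profile_ranks(p_a$z[idx, , drop = FALSE])
  rb <- profile_ranks(p_b$z[idx, , drop = FALSE])
  delta <- colMeans(ra - rb)
  keep <- abs(delta) >= min_shift
  out <- data.frame(roi = p_a$roi_names[keep], mean_rank_change = delta[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$mean_rank_change)), , drop = FALSE]
}

#' Per-subject CSCP maps and scores for a cohort
#'
#' For every subject, computes MPH-PBO, HAL-PBO and the within-session
#' placebo split-half map for one metric, plus subject-wise mean scores.
#'
#' @param cohort cohort list with `manifest`, `roi_ts`, `striatal_ts`,
#'   `cortical_idx`.
#' @param metric `"AD"`, `"ROR"` or `"ES"`.
#' @param equalize_null_length compute the drug and placebo profiles on
#'   half-length runs too, so the drug-placebo comparison carries the same
#'   sampling noise as the split-half null (calibration studies); default
#'   FALSE, matching the full-run convention.
#' @return list: `maps` (named list condition-pair -> list of per-subject
#'   `cscp_map`s), `scores` (long data.frame subject, condition_pair,
#'   score).
#' @export
cohort_cscp <- function(cohort, metric = c("ROR", "AD", "ES"),
                        equalize_null_length = FALSE) {
  metric <- match.arg(metric)
  fn <- switch(metric, AD = aggregate_divergence,
               ROR = rank_order_rearrangement, ES = entropy_shift)
  man <- cohort$manifest
  subjects <- unique(man$subject)
  idx <- cohort$cortical_idx
  cort <- function(key) {
    ts <- cohort$roi_ts[[key]]
    roi_timeseries(ts$values[, idx, drop = FALSE], ts$roi_names[idx], ts$tr_seconds)
  }
  pairs <- c("MPH-PBO", "HAL-PBO", "PBO-split")
  maps <- stats::setNames(vector("list", 3L), pairs)
  rows <- list()
  half <- function(ts) {
    ts$values <- ts$values[seq_len(nrow(ts$values) %/% 2L), , drop = FALSE]
    ts
  }
  for (s in subjects) {
    prof <- list()
    for (cond in c("PBO", "MPH", "HAL")) {
      key <- paste0(s, "_", cond)
      str <- cohort$striatal_ts[[key]]
      ct <- cort(key)
      if (equalize_null_length) { str <- half(str); ct <- half(ct) }
      prof[[cond]] <- connectivity_profile(str, ct, cond)
    }
    keyp <- paste0(s, "_PBO")
    halves <- split_half_profiles(cohort$striatal_ts[[keyp]], cort(keyp))
    ms <- list(`MPH-PBO` = fn(prof$MPH, prof$PBO),
               `HAL-PBO` = fn(prof$HAL, prof$PBO),
               `PBO-split` = fn(halves$first, halves$second))
    for (pr in pairs) {
      maps[[pr]][[s]] <- ms[[pr]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition_pair = pr, metric = metric,
        score = subject_cscp_score(ms[[pr]]), stringsAsFactors = FALSE)
    }
  }
  list(maps = maps, scores = do.call(rbind, rows))
}
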