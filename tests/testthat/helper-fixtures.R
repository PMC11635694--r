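# Small in-code fixtures shared across test files.

# profile_matrix built directly from a z matrix (voxels x ROIs)
mk_profile <- function(z, coords = NULL, condition = "A") {
  z <- as.matrix(z)
  if (is.null(coords)) coords <- cbind(seq_len(nrow(z)), 1L, 1L)
  structure(list(z = z, voxel_coords = coords,
                 roi_names = paste0("ROI", seq_len(ncol(z))),
                 condition = condition),
            class = "profile_matrix")
}

# cscp_map built directly from per-voxel values
mk_map <- function(values, coords = NULL, metric = "ROR") {
  if (is.null(coords)) coords <- cbind(seq_along(values), 1L, 1L)
  structure(list(values = values, voxel_coords = coords, metric = metric,
                 condition_pair = "A-B"),
            class = "cscp_map")
}

# dwell table directly from per-state total times
mk_dwell <- function(total_times) {
  k <- length(total_times)
  data.frame(state = seq_len(k), state_name = default_state_names(k),
             total_time_s = total_times, transitions = 1,
             persistence_s = total_times, stringsAsFactors = FALSE)
}

# naive run-length dwell oracle: explicit frame-by-frame loop
naive_dwell <- function(labels, tr, n_states) {
  total <- entries <- numeric(n_states)
  runs <- vector("list", n_states)
  cur <- labels[1L]; len <- 1L
  flush <- function(s, l) {
    entries[s] <<- entries[s] + 1L
    runs[[s]] <<- c(runs[[s]], l)
  }
  if (length(labels) > 1L) {
    for (t in 2:length(labels)) {
      if (labels[t] == cur) len <- len + 1L
      else { flush(cur, len); cur <- labels[t]; len <- 1L }
    }
  }
  flush(cur, len)
  for (s in seq_len(n_states)) total[s] <- sum(runs[[s]]) * tr
  data.frame(state = seq_len(n_states), total_time_s = total,
             transitions = entries,
             persistence_s = vapply(runs, function(r)
               if (length(r)) mean(r) * tr else NA_real_, numeric(1)))
}
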