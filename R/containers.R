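#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' ROI time-series container
#'
#' Frames-by-ROIs signal matrix with a repetition time, the unit every
#' pipeline stage consumes. Rows are frames in scan order; columns are
#' regions of interest.
#'
#' @param values numeric matrix, frames x ROIs.
#' @param roi_names character vector of unique ROI labels, one per column.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return An object of class `roi_timeseries` with fields `values`,
#'   `roi_names`, `tr_seconds`.
#' @export
roi_timeseries <- function(values, roi_names = colnames(values), tr_seconds = 2) {
  values <- as.matrix(values)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(values)))
  if (nrow(values) < 2L) stopf("roi_timeseries needs >= 2 frames, got %d", nrow(values))
  if (any(!is.finite(values))) stopf("roi_timeseries values must be finite")
  if (length(roi_names) != ncol(values)) stopf("roi_names length != column count")
  if (anyDuplicated(roi_names)) stopf("roi_names must be unique")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stopf("tr_seconds must be > 0")
  colnames(values) <- roi_names
  structure(list(values = values, roi_names = as.character(roi_names),
                 tr_seconds = as.numeric(tr_seconds)),
            class = "roi_timeseries")
}

#' Striatal voxel time-series container
#'
#' @param values numeric matrix, frames x voxels.
#' @param voxel_coords integer matrix (voxels x 3) of (i, j, k) grid
#'   coordinates; one row per column of `values`.
#' @param tr_seconds repetition time in seconds.
#' @return An object of class `voxel_timeseries`.
#' @export
voxel_timeseries <- function(values, voxel_coords, tr_seconds = 2) {
  values <- as.matrix(values)
  voxel_coords <- as.matrix(voxel_coords)
  if (ncol(voxel_coords) != 3L) stopf("voxel_coords must have 3 columns (i, j, k)")
  if (nrow(voxel_coords) != ncol(values))
    stopf("voxel_coords rows (%d) != voxel columns (%d)", nrow(voxel_coords), ncol(values))
  if (anyDuplicated(voxel_coords)) stopf("voxel_coords must be unique")
  structure(list(values = values, voxel_coords = voxel_coords,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "voxel_timeseries")
}

#' Set of CAP state centroids
#'
#' Holds the spatial maps of the transient network states (default eight:
#' FI-DMN, FPN, DMN, DAN, SN-1, SMO, SM-DMN, SN-2) used for frame
#' assignment; one row per state, one column per ROI.
#'
#' @param values numeric matrix, states x ROIs; every row must have nonzero
#'   variance.
#' @param state_names character vector of unique state labels.
#' @return An object of class `centroid_set`.
#' @export
centroid_set <- function(values, state_names = default_state_names(nrow(values))) {
  values <- as.matrix(values)
  if (length(state_names) != nrow(values)) stopf("state_names length != row count")
  if (anyDuplicated(state_names)) stopf("state_names must be unique")
  rv <- apply(values, 1L, stats::var)
  if (any(rv == 0)) stopf("centroid row(s) %s have zero variance",
                          paste(which(rv == 0), collapse = ", "))
  rownames(values) <- state_names
  structure(list(values = values, state_names = as.character(state_names)),
            class = "centroid_set")
}

#' Canonical transient-network-state names
#'
#' @param n number of states; the canonical eight labels are returned when
#'   `n == 8`, otherwise generic `state<k>` labels.
#' @return character vector of length `n`.
#' @export
default_state_names <- function(n) {
  canonical <- c("FI-DMN", "FPN", "DMN", "DAN", "SN-1", "SMO", "SM-DMN", "SN-2")
  if (n == length(canonical)) canonical else paste0("state", seq_len(n))
}
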