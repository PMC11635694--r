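# Readers/writers for the tab-separated matrix format and NIfTI extraction.
# All text writers round-trip through their readers to 1e-12.

parse_numeric_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (length(lines) < 2L) stopf("%s: need a header row plus >= 1 data row", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  body <- lines[-1L]
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  bad <- which(widths != ncol)
  if (length(bad))
    stopf("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad[1L] + 1L, widths[bad[1L]], ncol)
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L]
    line <- ((flat - 1L) %/% ncol) + 2L   # +1 header, +1 one-based
    col <- ((flat - 1L) %% ncol) + 1L
    stopf("%s: non-numeric cell at line %d, column %d", path, line, col)
  }
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  colnames(m) <- header
  m
}

write_numeric_table <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an ROI time-series matrix from tab-separated text
#'
#' Expects a header row of ROI names followed by one row per frame in scan
#' order. Malformed input (ragged rows, non-numeric cells) fails with the
#' offending line number.
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds (not stored in the file).
#' @param discard_initial number of leading frames to drop at load (the
#'   usual convention for discarding pre-steady-state frames); default 0.
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, tr_seconds = 2, discard_initial = 0L) {
  m <- parse_numeric_table(path)
  if (discard_initial > 0L) m <- m[-seq_len(discard_initial), , drop = FALSE]
  roi_timeseries(m, colnames(m), tr_seconds)
}

#' Write an ROI time-series matrix as tab-separated text
#'
#' @param ts a [roi_timeseries()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  write_numeric_table(ts$values, path)
}

#' Read / write voxel time series (tab-separated, coordinate header)
#'
#' Voxel columns are named `v<i>_<j>_<k>` from their grid coordinates so the
#' text format round-trips coordinates as well as values.
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds.
#' @return A [voxel_timeseries()].
#' @export
read_voxel_timeseries <- function(path, tr_seconds = 2) {
  m <- parse_numeric_table(path)
  parts <- strsplit(sub("^v", "", colnames(m)), "_", fixed = TRUE)
  coords <- do.call(rbind, lapply(parts, as.integer))
  voxel_timeseries(m, coords, tr_seconds)
}

#' @rdname read_voxel_timeseries
#' @param ts a [voxel_timeseries()].
#' @export
write_voxel_timeseries <- function(ts, path) {
  m <- ts$values
  colnames(m) <- sprintf("v%d_%d_%d", ts$voxel_coords[, 1L],
                         ts$voxel_coords[, 2L], ts$voxel_coords[, 3L])
  write_numeric_table(m, path)
}

#' Read / write a centroid matrix (states x ROIs) from tab-separated text
#'
#' First column `state` holds the state name; remaining columns are ROIs.
#'
#' @param path file path.
#' @return A [centroid_set()].
#' @export
read_centroids <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  states <- vapply(cells, `[`, "", 1L)
  vals <- lapply(cells, function(r) as.numeric(r[-1L]))
  m <- do.call(rbind, vals)
  colnames(m) <- header[-1L]
  centroid_set(m, states)
}

#' @rdname read_centroids
#' @param cen a [centroid_set()].
#' @export
write_centroids <- function(cen, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("state", colnames(cen$values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(cen$values)), function(i)
    paste(c(cen$state_names[i], sprintf("%.17g", cen$values[i, ])), collapse = "\t"),
    "")
  writeLines(body, con)
  invisible(path)
}

#' Extract time series from a 4D NIfTI volume
#'
#' In `roi-mean` mode, voxels sharing an atlas label are averaged per frame
#' and labels are reported in ascending numeric order (gaps in the label
#' numbering are fine: labels \{2, 9\} give two ROIs). In `voxelwise` mode,
#' every nonzero mask voxel contributes one column, ordered by (k, j, i)
#' ascending so downstream voxel maps are reproducible.
#'
#' @param image_path 4D NIfTI file.
#' @param atlas_path 3D integer-label NIfTI (roi-mean) or binary mask
#'   (voxelwise) on the same voxel grid.
#' @param mode `"roi-mean"` or `"voxelwise"`.
#' @param tr_seconds repetition time in seconds, or `"from header"` to take
#'   the 4th pixdim from the image header. A numeric value that disagrees
#'   with the header logs a warning and wins.
#' @param discard_initial leading frames to drop; default 0.
#' @return A [roi_timeseries()] (roi-mean) or [voxel_timeseries()]
#'   (voxelwise).
#' @export
extract_timeseries_from_nifti <- function(image_path, atlas_path,
                                          mode = c("roi-mean", "voxelwise"),
                                          tr_seconds = "from header",
                                          discard_initial = 0L) {
  mode <- match.arg(mode)
  img <- RNifti::readNifti(image_path)
  atlas <- RNifti::readNifti(atlas_path)
  dimg <- dim(img)
  if (length(dimg) != 4L) stopf("image must be 4D, got %d dims", length(dimg))
  if (!identical(dimg[1:3], dim(atlas)[1:3]))
    stopf("image grid (%s) != atlas grid (%s)",
          paste(dimg[1:3], collapse = "x"), paste(dim(atlas)[1:3], collapse = "x"))
  hdr_tr <- RNifti::pixdim(img)[4L]
  if (identical(tr_seconds, "from header")) {
    tr <- hdr_tr
    if (!is.finite(tr) || tr <= 0) stopf("image header has no usable TR; pass tr_seconds")
  } else {
    tr <- as.numeric(tr_seconds)
    if (is.finite(hdr_tr) && hdr_tr > 0 && abs(hdr_tr - tr) > 1e-6)
      warnf("TR mismatch: header %.4g s vs requested %.4g s; using %.4g", hdr_tr, tr, tr)
  }
  n_frames <- dimg[4L]
  vol <- array(as.numeric(img), dim = dimg)
  mat <- matrix(vol, nrow = prod(dimg[1:3]), ncol = n_frames)  # voxels x frames
  lab <- as.integer(round(as.numeric(atlas)))

  if (mode == "roi-mean") {
    labels <- sort(unique(lab[lab != 0L]))
    cols <- lapply(labels, function(l) {
      idx <- which(lab == l)
      if (length(idx) == 1L) mat[idx, ] else colMeans(mat[idx, , drop = FALSE])
    })
    out <- do.call(cbind, cols)
    if (discard_initial > 0L) out <- out[-seq_len(discard_initial), , drop = FALSE]
    roi_timeseries(out, paste0("label", labels), tr)
  } else {
    idx <- which(lab != 0L)
    co <- arrayInd(idx, dimg[1:3])
    ord <- order(co[, 3L], co[, 2L], co[, 1L])
    idx <- idx[ord]
    co <- co[ord, , drop = FALSE]
    out <- t(mat[idx, , drop = FALSE])
    if (discard_initial > 0L) out <- out[-seq_len(discard_initial), , drop = FALSE]
    voxel_timeseries(out, co, tr)
  }
}
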