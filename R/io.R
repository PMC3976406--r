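#' Write a scan as a NIfTI-1 4D volume
#'
#' The masked T x V data matrix is unpacked onto the full grid (zeros
#' outside the brain mask) and written with the voxel size in the header.
#'
#' @param scan an `rsn_scan`
#' @param path output file path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
write_scan_nifti <- function(scan, path) {
  grid <- scan$grid
  T <- nrow(scan$data)
  arr <- array(0, c(grid$dims, T))
  for (t in seq_len(T))
    arr[, , , t][grid$mask_idx] <- scan$data[t, ]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size_mm, 3), scan$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 4D volume into an `rsn_scan`
#'
#' @param path NIfTI file
#' @param grid the study [volume_grid()]; its mask defines the voxel
#'   ordering of the returned data matrix
#' @param subject,condition design labels to attach
#' @param tr_s repetition time; taken from the header when NULL
#' @return an `rsn_scan`
#' @export
read_scan_nifti <- function(path, grid, subject = "s1",
                            condition = "FD-T1", tr_s = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!all(dim(arr)[1:3] == grid$dims))
    stop("read_scan_nifti: image dimensions do not match the grid")
  T <- dim(arr)[4]
  data <- t(vapply(seq_len(T), function(t) arr[, , , t][grid$mask_idx],
                   numeric(grid$n_voxels)))
  if (is.null(tr_s)) tr_s <- RNifti::pixdim(img)[4]
  structure(list(subject = subject, day = condition_day(condition),
                 timepoint = condition_timepoint(condition),
                 condition = condition, tr_s = tr_s, data = data,
                 grid = grid),
            class = "rsn_scan")
}

#' Write a 3D mask or map as NIfTI-1
#'
#' @param v numeric/logical vector over in-mask voxels, or a full 3D array
#' @param grid the [volume_grid()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_map_nifti <- function(v, grid, path) {
  arr <- if (length(dim(v)) == 3) v else vec_to_vol(as.numeric(v), grid)
  arr <- arr * 1   # logical volumes are written as numeric
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a component set to disk
#'
#' Maps as a NIfTI-1 4D image (K volumes), time courses as TSV, and a
#' plain-text JSON-like sidecar with K, seed and variance retained.
#'
#' @param set a `component_set`
#' @param grid the [volume_grid()]
#' @param prefix output path prefix
#' @return character vector of written paths, invisibly
#' @export
write_component_set <- function(set, grid, prefix) {
  arr <- array(0, c(grid$dims, set$K))
  for (k in seq_len(set$K))
    arr[, , , k][grid$mask_idx] <- set$maps[k, ]
  nii <- paste0(prefix, "_maps.nii.gz")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size_mm, 3), 1)
  RNifti::writeNifti(img, nii)
  tsv <- paste0(prefix, "_courses.tsv")
  utils::write.table(set$courses, tsv, sep = "\t", row.names = FALSE,
                     col.names = paste0("ic", seq_len(set$K)))
  sidecar <- paste0(prefix, "_info.txt")
  writeLines(c(sprintf("K: %d", set$K),
               sprintf("seed: %d", as.integer(set$seed)),
               sprintf("var_retained: %.6f", set$var_retained)), sidecar)
  invisible(c(nii, tsv, sidecar))
}

#' Write cluster membership of a grouping result as CSV
#'
#' One row per (cluster label, subject, day, timepoint, component index).
#'
#' @param clusters list of `component_cluster`s
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_cluster_membership <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl)
    cbind(cluster = cl$label, cl$members)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
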