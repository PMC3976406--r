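#' Volumetric grid with brain mask
#'
#' Defines the common sampling grid all scans in a study share: integer
#' dimensions, an isotropic voxel size in mm, and a binary brain mask.
#' When no mask is supplied, an inscribed ellipsoid covering roughly 40%
#' of the box is used, which leaves a margin so smoothing kernels do not
#' wrap around the volume edges.
#'
#' @param dims integer triple (nx, ny, nz), each >= 4.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 3, so
#'   each voxel occupies 27 mm^3).
#' @param brain_mask optional logical array of dimension `dims`; must be
#'   nonempty.
#' @return an object of class `volume_grid` with fields `dims`,
#'   `voxel_size_mm`, `brain_mask` (logical array), `mask_idx` (linear
#'   indices of in-mask voxels) and `n_voxels`.
#' @export
volume_grid <- function(dims, voxel_size_mm = 3, brain_mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop("volume_grid: dims must be a triple with every dimension >= 4")
  if (voxel_size_mm <= 0) stop("volume_grid: voxel_size_mm must be positive")
  if (is.null(brain_mask)) {
    cx <- (dims + 1) / 2
    semi <- 0.45 * dims
    ii <- slice.index(array(0, dims), 1)
    jj <- slice.index(array(0, dims), 2)
    kk <- slice.index(array(0, dims), 3)
    brain_mask <- ((ii - cx[1]) / semi[1])^2 + ((jj - cx[2]) / semi[2])^2 +
      ((kk - cx[3]) / semi[3])^2 <= 1
  }
  brain_mask <- array(as.logical(brain_mask), dims)
  if (!any(brain_mask)) stop("volume_grid: brain_mask is empty")
  structure(
    list(dims = dims, voxel_size_mm = voxel_size_mm, brain_mask = brain_mask,
         mask_idx = which(brain_mask), n_voxels = sum(brain_mask)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d @ %g mm, %d brain voxels\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm, x$n_voxels))
  invisible(x)
}

# masked-vector <-> full-array conversions; all per-voxel data in the
# package travel as vectors over grid$mask_idx in fixed scan order.
vec_to_vol <- function(v, grid, fill = 0) {
  a <- array(fill, grid$dims)
  a[grid$mask_idx] <- v
  a
}

vol_to_vec <- function(a, grid) a[grid$mask_idx]

# Gaussian FWHM (mm) <-> kernel sd in voxels
fwhm_to_sd_vox <- function(fwhm_mm, voxel_size_mm)
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm

#' Smooth a 3D array with an isotropic Gaussian kernel
#'
#' FFT-based circular convolution with a periodised Gaussian kernel.
#' `sd_vox = 0` returns the input unchanged.
#'
#' @param a numeric 3D array
#' @param sd_vox kernel standard deviation in voxel units
#' @return smoothed array of the same dimension
#' @keywords internal
gaussian_smooth <- function(a, sd_vox) {
  if (sd_vox <= 0) return(a)
  d <- dim(a)
  kf <- gaussian_kernel_fft(d, sd_vox)
  Re(stats::fft(stats::fft(a) * kf, inverse = TRUE)) / prod(d)
}

# FFT of a periodised, sum-normalised isotropic Gaussian kernel
gaussian_kernel_fft <- function(d, sd_vox) {
  ax <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-x^2 / (2 * sd_vox^2))
  }
  k <- outer(outer(ax(d[1]), ax(d[2])), ax(d[3]))
  dim(k) <- d
  stats::fft(k / sum(k))
}

# seeded RNG scope: evaluates expr under set.seed(seed) and restores the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable small sub-seed derived from a user seed and a stream index
sub_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483629
  as.integer(s) + 1L
}

#' Dice overlap between two voxel index sets
#' @param a,b integer vectors of voxel indices (any common indexing)
#' @return 2|a n b| / (|a| + |b|); 0 when both are empty
#' @export
dice_overlap <- function(a, b) {
  if (length(a) + length(b) == 0L) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
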