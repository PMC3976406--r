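#' Build a synthetic network atlas
#'
#' Places `n_networks` networks on the grid, each the union of a few
#' spherical core blobs, and smooths each core indicator with an isotropic
#' Gaussian to obtain the network's spatial weight map. Cores are pairwise
#' disjoint across all networks (the map supports may overlap after
#' smoothing, as real resting-state networks do). With `fwhm_mm = 0` the
#' maps equal their unsmoothed blob indicators.
#'
#' @param grid a [volume_grid()]
#' @param n_networks number of networks (>= 2)
#' @param fwhm_mm smoothing kernel FWHM in mm (>= 0; default 6)
#' @param seed integer seed; the atlas is a deterministic function of
#'   (grid, n_networks, fwhm_mm, seed)
#' @param blobs_per_network spherical cores per network (default 2)
#' @param core_radius_mm radius of each core sphere in mm (default 6)
#' @param support_thresh fraction of the map maximum below which voxels are
#'   excluded from the support (default 0.25, i.e. the network
#'   extent excludes the outer smoothing halo)
#' @return object of class `network_atlas`: `grid`, `maps` (N x V matrix of
#'   nonnegative weights over in-mask voxels, max 1 per map), `core_masks`
#'   (N x V logical), `supports` (N x V logical), `centers` (list of voxel
#'   coordinate matrices)
#' @export
make_atlas <- function(grid, n_networks, fwhm_mm = 6, seed = 1L,
                       blobs_per_network = 2L, core_radius_mm = 6,
                       support_thresh = 0.25) {
  stopifnot(inherits(grid, "volume_grid"))
  if (n_networks < 2) stop("make_atlas: n_networks must be >= 2")
  if (fwhm_mm < 0) stop("make_atlas: fwhm_mm must be >= 0")
  r_vox <- core_radius_mm / grid$voxel_size_mm
  d <- grid$dims

  # candidate centers: in-mask voxels whose core sphere lies fully in-mask
  coords <- arrayInd(grid$mask_idx, d)
  off <- sphere_offsets(r_vox)
  ok <- vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[i, ]
    q <- sweep(off, 2, p, "+")
    if (any(q < 1) || any(q[, 1] > d[1]) || any(q[, 2] > d[2]) || any(q[, 3] > d[3]))
      return(FALSE)
    all(grid$brain_mask[q])
  }, logical(1))
  cand <- coords[ok, , drop = FALSE]
  n_blobs <- n_networks * blobs_per_network
  if (nrow(cand) < n_blobs)
    stop(sprintf(paste0("make_atlas: grid too small to place %d disjoint cores ",
                        "of radius %g mm (only %d feasible centers)"),
                 n_blobs, core_radius_mm, nrow(cand)))

  # spheres of radius r are voxelwise disjoint when centers are farther
  # apart than 2r; greedy placement is retried over seeded shuffles
  min_d2 <- (2 * r_vox)^2 + 1e-9
  centers <- matrix(0L, 0, 3)
  for (attempt in seq_len(50)) {
    picked <- with_seed(sub_seed(seed, 7000 + attempt), {
      ord <- sample.int(nrow(cand))
      pk <- matrix(0L, 0, 3)
      for (i in ord) {
        p <- cand[i, ]
        if (nrow(pk) == 0L || all(colSums((t(pk) - p)^2) >= min_d2)) {
          pk <- rbind(pk, p)
          if (nrow(pk) == n_blobs) break
        }
      }
      pk
    })
    if (nrow(picked) == n_blobs) {
      centers <- picked
      break
    }
  }
  if (nrow(centers) < n_blobs)
    stop(sprintf(paste0("make_atlas: grid too small to place %d disjoint cores ",
                        "of radius %g mm (placed %d before exhausting candidates)"),
                 n_blobs, core_radius_mm, nrow(centers)))

  sd_vox <- fwhm_to_sd_vox(fwhm_mm, grid$voxel_size_mm)
  V <- grid$n_voxels
  maps <- matrix(0, n_networks, V)
  cores <- matrix(FALSE, n_networks, V)
  ctr_list <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    rows <- ((k - 1) * blobs_per_network + 1):(k * blobs_per_network)
    ctr_list[[k]] <- centers[rows, , drop = FALSE]
    ind <- array(0, d)
    for (r in rows) {
      q <- sweep(off, 2, centers[r, ], "+")
      ind[q] <- 1
    }
    sm <- gaussian_smooth(ind, sd_vox)
    m <- vol_to_vec(sm, grid)
    m[m < 0] <- 0
    if (max(m) > 0) m <- m / max(m)
    maps[k, ] <- m
    cores[k, ] <- vol_to_vec(ind, grid) > 0
  }
  supports <- maps > support_thresh
  supports <- supports | cores  # cores always inside their support
  structure(
    list(grid = grid, maps = maps, core_masks = cores, supports = supports,
         centers = ctr_list, fwhm_mm = fwhm_mm, seed = seed),
    class = "network_atlas")
}

# integer offsets of voxels within a sphere of radius r (voxels)
sphere_offsets <- function(r) {
  ri <- ceiling(r)
  g <- as.matrix(expand.grid(-ri:ri, -ri:ri, -ri:ri))
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  colnames(g) <- NULL
  g
}

#' @export
print.network_atlas <- function(x, ...) {
  cat(sprintf("<network_atlas> %d networks, core %d voxels each, fwhm %g mm\n",
              nrow(x$maps), sum(x$core_masks[1, ]), x$fwhm_mm))
  invisible(x)
}

#' Specify a planted condition-dependent regional amplitude effect
#'
#' Declares that inside `target_region` the amplitude of network
#' `target_network` is multiplied by a condition-specific gain. A gain
#' above 1 is an enhancement, below 1 a suppression; conditions absent
#' from `condition_gains` keep gain 1.
#'
#' @param target_network network index into the atlas
#' @param target_region logical V-vector (over in-mask voxels) or integer
#'   vector of in-mask voxel positions; must lie inside the network support
#' @param condition_gains named numeric vector, e.g. `c("WD-T3" = 1.5)`;
#'   all gains must be > 0
#' @param atlas optional atlas for validating the containment invariant
#' @return object of class `effect_spec`
#' @export
effect_spec <- function(target_network, target_region, condition_gains,
                        atlas = NULL) {
  if (is.logical(target_region)) target_region <- which(target_region)
  target_region <- as.integer(target_region)
  if (length(target_region) == 0L) stop("effect_spec: empty target_region")
  if (any(condition_gains <= 0)) stop("effect_spec: gains must be > 0")
  if (is.null(names(condition_gains)))
    stop("effect_spec: condition_gains must be named by condition label")
  if (!is.null(atlas)) {
    if (target_network < 1 || target_network > nrow(atlas$maps))
      stop("effect_spec: target_network out of range")
    if (!all(atlas$supports[target_network, target_region]))
      stop("effect_spec: target_region must lie inside the network support")
  }
  structure(list(target_network = as.integer(target_network),
                 target_region = target_region,
                 condition_gains = condition_gains),
            class = "effect_spec")
}
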