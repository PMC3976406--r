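#' Within-subject contrast specification
#'
#' Named condition weights that must sum to zero with at least two
#' nonzero entries. The study's combined exhaustion contrast is
#' `c("WD-T3" = 3, "WD-T1" = -1, "FD-T1" = -1, "FD-T3" = -1)`: it pools
#' the three inequalities WD-T3 > FD-T3, WD-T3 > WD-T1 and WD-T3 > FD-T1
#' into one linear contrast, leaving WD-T2 out of the voxelwise test.
#'
#' @param weights named numeric vector of condition weights
#' @return object of class `contrast_spec`
#' @export
contrast_spec <- function(weights = c("WD-T3" = 3, "WD-T1" = -1,
                                      "FD-T1" = -1, "FD-T3" = -1)) {
  if (is.null(names(weights))) stop("contrast_spec: weights must be named")
  if (abs(sum(weights)) > 1e-12) stop("contrast_spec: weights must sum to 0")
  if (sum(weights != 0) < 2) stop("contrast_spec: need >= 2 nonzero weights")
  structure(list(weights = weights), class = "contrast_spec")
}

#' Voxelwise repeated-measures contrast t-map
#'
#' For each subject the condition maps are combined into a contrast score
#' `c_s = sum_cond w_cond * y_(s,cond)` per voxel; the map of one-sample
#' t statistics `t = mean(c) / (SD(c) / sqrt(n))` with n - 1 degrees of
#' freedom is returned (two-tailed). This is exact for a single
#' within-subject contrast of the day x timepoint repeated-measures
#' ANOVA, and is invariant to adding any subject-specific constant map.
#' Zero-variance voxels are capped at +/- 1e6 and flagged.
#'
#' @param maps named list: one entry per condition holding an
#'   n_subjects x V matrix with consistent row order; every condition
#'   with nonzero weight must be present for every subject (no NA rows)
#' @param spec a [contrast_spec()]
#' @return a `stat_map` (`values`, `df = n - 1`, `tail = "two"`,
#'   `n_capped`) with the per-subject `scores` matrix attached
#' @export
contrast_tmap <- function(maps, spec = contrast_spec()) {
  stopifnot(inherits(spec, "contrast_spec"))
  w <- spec$weights[spec$weights != 0]
  missing_cond <- setdiff(names(w), names(maps))
  if (length(missing_cond) > 0)
    stop(sprintf("contrast_tmap: missing condition maps: %s",
                 paste(missing_cond, collapse = ", ")))
  n <- nrow(maps[[names(w)[1]]])
  if (n < 3) stop("contrast_tmap: need >= 3 subjects")
  for (cond in names(w)) {
    m <- maps[[cond]]
    if (nrow(m) != n) stop("contrast_tmap: unequal subject counts across conditions")
    if (anyNA(m)) {
      bad <- rownames(m)[apply(is.na(m), 1, any)]
      stop(sprintf("contrast_tmap: subject(s) %s missing condition %s",
                   paste(bad, collapse = ", "), cond))
    }
  }
  scores <- Reduce(`+`, lapply(names(w), function(cond) w[cond] * maps[[cond]]))
  m <- colMeans(scores)
  s <- sqrt(colSums(sweep(scores, 2, m)^2) / (n - 1))
  # variance below floating-point resolution of the input maps counts as
  # zero, so exactly planted shifts hit the cap instead of 0/0 noise
  tiny <- 1e-10 * max(abs(vapply(maps[names(w)], function(mm)
    max(abs(range(mm))), numeric(1))), .Machine$double.xmin)
  zero_var <- s <= tiny
  zero_mean <- abs(m) <= tiny
  t <- ifelse(!zero_var, m / (s / sqrt(n)),
              ifelse(zero_mean, 0, sign(m) * T_CAP))
  out <- structure(list(values = pmin(pmax(t, -T_CAP), T_CAP), df = n - 1L,
                        tail = "two", n_capped = sum(zero_var & !zero_mean)),
                   class = "stat_map")
  attr(out, "scores") <- scores
  out
}

#' Estimate map smoothness as a Gaussian FWHM
#'
#' Gradient estimator: along each axis, with `s^2` the variance of
#' first differences between neighbouring in-mask voxels and `sigma^2`
#' the map variance, the implied Gaussian kernel FWHM is
#' `voxel * sqrt(4 log 2) * sigma / s`; axis estimates are averaged.
#' Spatially white noise yields about 1.18 voxels (the discrete
#' resolution floor).
#'
#' @param map_vec numeric vector over in-mask voxels (nonconstant)
#' @param grid the [volume_grid()]
#' @return estimated FWHM in mm
#' @export
estimate_smoothness <- function(map_vec, grid) {
  if (stats::sd(map_vec) == 0)
    stop("estimate_smoothness: constant map has no defined smoothness")
  a <- vec_to_vol(map_vec, grid, fill = NA)
  a[!grid$brain_mask] <- NA
  sig2 <- stats::var(map_vec)
  d <- grid$dims
  fw <- numeric(3)
  for (ax in 1:3) {
    idx1 <- lapply(seq_along(d), function(i)
      if (i == ax) seq_len(d[i] - 1) else seq_len(d[i]))
    idx2 <- lapply(seq_along(d), function(i)
      if (i == ax) seq_len(d[i] - 1) + 1 else seq_len(d[i]))
    diffs <- do.call(`[`, c(list(a), idx2)) - do.call(`[`, c(list(a), idx1))
    diffs <- diffs[!is.na(diffs)]
    s2 <- stats::var(diffs)
    fw[ax] <- grid$voxel_size_mm * sqrt(4 * log(2) * sig2 / s2)
  }
  mean(fw)
}

# kernel sd (voxels) whose smoothed discrete field re-estimates to the
# requested FWHM under the gradient estimator; 0 at or below the
# white-noise floor
fwhm_to_kernel_sd <- function(fwhm_mm, voxel_size_mm) {
  est_for_sd <- function(sk) {
    rho1 <- exp(-1 / (4 * sk^2))
    voxel_size_mm * sqrt(4 * log(2) / (2 * (1 - rho1)))
  }
  floor_fwhm <- voxel_size_mm * sqrt(2 * log(2))   # white-noise limit
  if (fwhm_mm <= floor_fwhm) return(0)
  stats::uniroot(function(sk) est_for_sd(sk) - fwhm_mm,
                 lower = 1e-3, upper = 100)$root
}

# sizes of 6-connected components among the given linear voxel indices;
# returns integer(0) when empty. membership=TRUE returns per-voxel labels.
connected_components <- function(lin_idx, dims, membership = FALSE) {
  nvox <- length(lin_idx)
  if (nvox == 0L)
    return(if (membership) integer(0) else integer(0))
  ord <- order(lin_idx)
  lin <- lin_idx[ord]
  coord <- arrayInd(lin, dims)
  nxy <- dims[1] * dims[2]
  labels <- integer(nvox)
  lab <- 0L
  for (i in seq_len(nvox)) {
    if (labels[i] > 0L) next
    lab <- lab + 1L
    stack <- i
    labels[i] <- lab
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      x <- coord[cur, 1]; y <- coord[cur, 2]; z <- coord[cur, 3]
      l <- lin[cur]
      nb <- c(if (x > 1) l - 1L, if (x < dims[1]) l + 1L,
              if (y > 1) l - dims[1], if (y < dims[2]) l + dims[1],
              if (z > 1) l - nxy, if (z < dims[3]) l + nxy)
      # findInterval locates the last lin <= nb; keep exact hits only
      pos <- findInterval(nb, lin)
      pos <- pos[pos > 0L]
      hit <- pos[lin[pos] %in% nb & labels[pos] == 0L]
      if (length(hit) > 0L) {
        labels[hit] <- lab
        stack <- c(stack, hit)
      }
    }
  }
  if (membership) {
    out <- integer(nvox)
    out[ord] <- labels
    return(out)
  }
  tabulate(labels)
}

#' Empirical spatial autocorrelation spectrum of residual maps
#'
#' Estimates the stationary spatial autocovariance of a set of maps on
#' the grid (mask-aware: lagged products are normalised by the number of
#' in-mask voxel pairs at each lag, computed by FFT), averages it over
#' maps, and returns the corresponding power spectrum (negative values
#' clipped), suitable for colouring white noise in
#' [cluster_threshold_mc()]. Unlike a scalar FWHM fitted to lag-1
#' differences, the empirical spectrum preserves heavy autocorrelation
#' tails and anisotropy, which govern the null cluster-size
#' distribution.
#'
#' @param maps matrix (rows = maps, columns = in-mask voxels)
#' @param grid the [volume_grid()]
#' @return 3D array of spectral weights (the FFT of the normalised ACF)
#' @export
estimate_acf_spectrum <- function(maps, grid) {
  if (is.null(dim(maps))) maps <- matrix(maps, 1)
  d <- grid$dims
  N <- prod(d)
  Fm <- stats::fft(grid$brain_mask * 1)
  npairs <- Re(stats::fft(Fm * Conj(Fm), inverse = TRUE)) / N
  acc <- 0
  for (i in seq_len(nrow(maps))) {
    a <- vec_to_vol(maps[i, ], grid)
    Fa <- stats::fft(a)
    acc <- acc + Re(stats::fft(Fa * Conj(Fa), inverse = TRUE)) / N
  }
  acf <- acc / pmax(npairs, 1)
  acf <- acf / acf[1]
  spec <- Re(stats::fft(acf))
  spec[spec < 0] <- 0
  spec
}

#' Monte-Carlo minimum cluster size
#'
#' Simulates `n_iter` null Gaussian random fields on the grid at the given
#' smoothness, applies the two-tailed voxel threshold `voxel_p`, records
#' the maximum 6-connected cluster size per iteration (positive and
#' negative suprathreshold voxels clustered separately), and returns the
#' smallest size k whose null exceedance frequency is below `alpha`.
#' Supplying `alpha = 0.05 / N` implements the network-count adjustment
#' for N tested networks.
#'
#' @param grid a [volume_grid()]
#' @param fwhm_mm smoothness of the constituent fields (e.g. from
#'   [estimate_smoothness()] on the per-subject maps)
#' @param voxel_p two-tailed voxel-level threshold (default 0.01)
#' @param alpha cluster-level false-positive rate (default 0.05)
#' @param n_iter Monte-Carlo iterations (default 500)
#' @param seed integer seed (required, logged in the result)
#' @param acf_spectrum optional 3D spectral weight array from
#'   [estimate_acf_spectrum()]; when given, null fields are white noise
#'   coloured by this empirical spectrum instead of a Gaussian kernel,
#'   and `fwhm_mm` is recorded but not used
#' @param df when given, each null field is the one-sample t-map of
#'   `df + 1` independent smooth Gaussian fields thresholded at the
#'   matching t quantile — the null of a random-effects contrast map;
#'   NULL (default) simulates a single Gaussian field with the normal
#'   quantile. Simulated fields carry their exact analytic variance (no
#'   per-realisation standardisation, which would condition away
#'   large-excursion realisations and bias the threshold low)
#' @return integer minimum cluster size in voxels, with the simulated
#'   max-size distribution in attribute `max_sizes`
#' @export
cluster_threshold_mc <- function(grid, fwhm_mm, voxel_p = 0.01,
                                 alpha = 0.05, n_iter = 500, seed,
                                 acf_spectrum = NULL, df = NULL) {
  if (voxel_p <= 0 || voxel_p >= 1) stop("cluster_threshold_mc: bad voxel_p")
  if (alpha <= 0 || alpha >= 1) stop("cluster_threshold_mc: bad alpha")
  d <- grid$dims
  kf <- NULL
  field_sd <- 1
  if (!is.null(acf_spectrum)) {
    kf <- sqrt(acf_spectrum)
    field_sd <- sqrt(sum(acf_spectrum) / prod(d))
  } else {
    sk <- fwhm_to_kernel_sd(fwhm_mm, grid$voxel_size_mm)
    if (sk > 0) {
      kf <- gaussian_kernel_fft(d, sk)
      # exact sd of white noise circularly convolved with the kernel
      field_sd <- sqrt(sum(Mod(kf)^2) / prod(d))
    }
  }
  n_fields <- if (is.null(df)) 1L else df + 1L
  thr <- if (is.null(df)) stats::qnorm(1 - voxel_p / 2) else
    stats::qt(1 - voxel_p / 2, df)
  gen_field <- function() {
    f <- array(stats::rnorm(prod(d)), d)
    if (!is.null(kf))
      f <- Re(stats::fft(stats::fft(f) * kf, inverse = TRUE)) / prod(d)
    f[grid$mask_idx] / field_sd
  }
  max_sizes <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    if (is.null(df)) {
      v <- gen_field()
    } else {
      S <- vapply(seq_len(n_fields), function(j) gen_field(),
                  numeric(grid$n_voxels))
      m <- rowMeans(S)
      s <- sqrt(rowSums((S - m)^2) / df)
      v <- ifelse(s > 0, m / (s / sqrt(n_fields)), 0)
    }
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra <- grid$mask_idx[sgn * v > thr]
      if (length(supra) > 0L)
        mx <- max(mx, connected_components(supra, d))
    }
    mx
  }, integer(1)))
  k <- 1L
  while (mean(max_sizes >= k) >= alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes, fwhm_mm = fwhm_mm, seed = seed)
}

#' Extract suprathreshold clusters from a t-map
#'
#' Applies the two-tailed voxel threshold, groups positive and negative
#' suprathreshold voxels separately by 6-connectivity (face neighbours;
#' diagonal contact does not connect), drops clusters below `min_size`
#' voxels, and summarises each survivor with its |t|-weighted centre of
#' mass in mm (origin at the grid centre), extension in mm^3, average t
#' and signed maximum-|t|.
#'
#' @param tmap a `stat_map` over the grid's in-mask voxels
#' @param grid the [volume_grid()]
#' @param voxel_p two-tailed voxel threshold (default 0.01)
#' @param min_size minimum cluster size in voxels (default 1)
#' @return list of `region_cluster` objects (fields `voxels` — positions
#'   in the mask-vector indexing —, `lin_idx`, `center_of_mass_mm`,
#'   `extension_mm3`, `avg_t`, `max_t`, `sign`) plus a `report`
#'   data.frame attached as attribute
#' @export
extract_clusters <- function(tmap, grid, voxel_p = 0.01, min_size = 1L) {
  stopifnot(inherits(tmap, "stat_map"))
  if (min_size < 1) stop("extract_clusters: min_size must be >= 1")
  thr <- stats::qt(1 - voxel_p / 2, df = tmap$df)
  d <- grid$dims
  center <- (d + 1) / 2
  out <- list()
  for (sgn in c(1, -1)) {
    sel <- which(sgn * tmap$values > thr)
    if (length(sel) == 0L) next
    lin <- grid$mask_idx[sel]
    memb <- connected_components(lin, d, membership = TRUE)
    for (lab in unique(memb)) {
      inside <- memb == lab
      if (sum(inside) < min_size) next
      vox <- sel[inside]
      lin_c <- lin[inside]
      tv <- tmap$values[vox]
      w <- abs(tv) / sum(abs(tv))
      com <- (colSums(arrayInd(lin_c, d) * w) - center) * grid$voxel_size_mm
      out[[length(out) + 1L]] <- structure(
        list(voxels = vox, lin_idx = lin_c,
             center_of_mass_mm = com,
             extension_mm3 = length(vox) * grid$voxel_size_mm^3,
             avg_t = mean(tv), max_t = tv[which.max(abs(tv))],
             sign = if (sgn > 0) "enhancement" else "suppression"),
        class = "region_cluster")
    }
  }
  report <- if (length(out) == 0) {
    data.frame(region = integer(0), sign = character(0), x_mm = numeric(0),
               y_mm = numeric(0), z_mm = numeric(0), avg_t = numeric(0),
               max_t = numeric(0), extension_mm3 = numeric(0))
  } else {
    do.call(rbind, lapply(seq_along(out), function(i) {
      cl <- out[[i]]
      data.frame(region = i, sign = cl$sign,
                 x_mm = cl$center_of_mass_mm[1],
                 y_mm = cl$center_of_mass_mm[2],
                 z_mm = cl$center_of_mass_mm[3],
                 avg_t = cl$avg_t, max_t = cl$max_t,
                 extension_mm3 = cl$extension_mm3)
    }))
  }
  attr(out, "report") <- report
  out
}

#' Regional component scores
#'
#' Averages each supplied best-fit component z-map over the voxels of a
#' region, one row per subject x scan.
#'
#' @param maps named list of entries, each with `subject`, `condition`
#'   and `map` (numeric vector over mask voxels)
#' @param region a `region_cluster` or an integer vector of mask-vector
#'   voxel positions
#' @return data.frame (subject, condition, score)
#' @export
regional_scores <- function(maps, region) {
  vox <- if (inherits(region, "region_cluster")) region$voxels else as.integer(region)
  if (length(vox) == 0L) stop("regional_scores: empty region")
  do.call(rbind, lapply(maps, function(e)
    data.frame(subject = e$subject, condition = e$condition,
               score = mean(e$map[vox]))))
}

#' Scan x exhaustion ANCOVA on regional scores
#'
#' Ordinary least squares of `score ~ scan + vas + scan:vas` with partial
#' F tests from nested residual sums of squares: the VAS covariate is
#' tested against the scan-only model, the interaction against the
#' additive model. P values are reported uncorrected.
#'
#' @param table data.frame with columns `subject`, `scan` (factor-like,
#'   >= 2 levels with >= 3 subjects each), `score`, `vas`
#' @return list with `vas` and `interaction`, each
#'   (F, df1, df2, p), plus the fitted models
#' @export
ancova_scores <- function(table) {
  need <- c("subject", "scan", "score", "vas")
  if (!all(need %in% names(table)))
    stop("ancova_scores: table must have subject, scan, score, vas")
  table$scan <- factor(table$scan)
  if (nlevels(table$scan) < 2) stop("ancova_scores: need >= 2 scan levels")
  if (any(tabulate(table$scan) < 3))
    stop("ancova_scores: need >= 3 subjects per scan level")
  m0 <- stats::lm(score ~ scan, data = table)
  m1 <- stats::lm(score ~ scan + vas, data = table)
  m2 <- stats::lm(score ~ scan * vas, data = table)
  if (any(is.na(stats::coef(m2))))
    stop("ancova_scores: collinear design (aliased coefficients)")
  ss_total <- sum((table$score - mean(table$score))^2)
  partial_f <- function(small, big) {
    rss0 <- sum(stats::residuals(small)^2)
    rss1 <- sum(stats::residuals(big)^2)
    df1 <- small$df.residual - big$df.residual
    df2 <- big$df.residual
    if (rss0 <= 1e-12 * ss_total) {
      # the reduced model already fits to numerical precision: no
      # evidence for the extra term
      return(c(F = 0, df1 = df1, df2 = df2, p = 1))
    }
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    c(F = f, df1 = df1, df2 = df2,
      p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  list(vas = partial_f(m0, m1), interaction = partial_f(m1, m2),
       models = list(scan_only = m0, additive = m1, full = m2))
}
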