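T_CAP <- 1e6  # zero-variance voxels are capped here and flagged

#' Random-effects one-sample t-map of a component cluster
#'
#' Per voxel, `t = mean / (SD / sqrt(n))` across the cluster's n member
#' maps with n - 1 degrees of freedom, treating subjects as random
#' observations. Voxels with zero between-member variance are capped at
#' +/- 1e6 (0 when the mean is also 0) and counted in `n_capped`.
#'
#' @param cluster a `component_cluster` with >= 3 members
#' @return object of class `stat_map`: `values`, `df`, `tail` ("one"),
#'   `n_capped`
#' @export
cluster_tmap <- function(cluster) {
  X <- cluster$member_maps
  n <- nrow(X)
  if (n < 3) stop("cluster_tmap: need >= 3 member maps")
  m <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, m)^2) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)),
              ifelse(m == 0, 0, sign(m) * T_CAP))
  t <- pmin(pmax(t, -T_CAP), T_CAP)
  structure(list(values = t, df = n - 1L, tail = "one",
                 n_capped = sum(s == 0 & m != 0)),
            class = "stat_map")
}

#' Threshold a cluster t-map into an RSN template mask
#'
#' Bonferroni correction over the brain voxels at voxel level `alpha`,
#' one-tailed positive (network membership is positive engagement): the
#' mask keeps voxels with `t >= qt(1 - alpha / n_tests, df)`. An empty
#' mask raises a warning and flags the template unusable.
#'
#' @param tmap a `stat_map`
#' @param alpha corrected voxel-level alpha (default 0.05)
#' @param n_tests number of tests, i.e. brain voxels
#' @param label template label
#' @return object of class `template_rsn`: `label`, `tmap`, `df`, `mask`
#'   (logical), `alpha`, `correction` ("bonferroni"), `threshold`, `usable`
#' @export
make_template_mask <- function(tmap, alpha = 0.05, n_tests,
                               label = "RSN") {
  stopifnot(inherits(tmap, "stat_map"))
  thr <- stats::qt(1 - alpha / n_tests, df = tmap$df)
  mask <- tmap$values >= thr
  usable <- any(mask)
  if (!usable)
    warning(sprintf("make_template_mask: template '%s' has an empty mask",
                    label))
  structure(list(label = label, tmap = tmap$values, df = tmap$df,
                 mask = mask, alpha = alpha, correction = "bonferroni",
                 threshold = thr, usable = usable),
            class = "template_rsn")
}

#' Goodness of fit of a component map to a template mask
#'
#' Mean z-score inside the template mask minus the mean z-score outside
#' it (outside = brain mask minus template mask).
#'
#' @param map numeric vector of component z-scores over brain voxels
#' @param mask logical vector of the same length, neither empty nor full
#' @return scalar goodness-of-fit
#' @export
goodness_of_fit <- function(map, mask) {
  if (length(map) != length(mask))
    stop("goodness_of_fit: map and mask lengths differ")
  if (!any(mask) || all(mask))
    stop("goodness_of_fit: degenerate mask (empty or full)")
  mean(map[mask]) - mean(map[!mask])
}

#' Select the best-fitting component for a template
#'
#' Argmax of [goodness_of_fit()] over a component set's maps; ties go to
#' the lowest component index.
#'
#' @param set a `component_set`
#' @param template a usable `template_rsn`
#' @return list with `index`, `gof`, `gofs` (all K values), `subject`,
#'   `day`, `timepoint`, `condition`
#' @export
select_best_fit <- function(set, template) {
  stopifnot(inherits(template, "template_rsn"))
  if (!template$usable)
    stop("select_best_fit: template is flagged unusable (empty mask)")
  gofs <- apply(set$maps, 1, goodness_of_fit, mask = template$mask)
  idx <- which.max(gofs)   # which.max returns the first (lowest) maximum
  list(index = idx, gof = gofs[idx], gofs = gofs, subject = set$subject,
       day = set$day, timepoint = set$timepoint, condition = set$condition)
}

#' Label group clusters against reference network maps
#'
#' For each reference map (e.g. the generator's true networks, or
#' user-supplied reference RSNs), picks the cluster whose centroid has the
#' highest absolute spatial correlation with it.
#'
#' @param clusters list of `component_cluster`s
#' @param reference_maps N x V matrix of reference network maps
#' @return data.frame with `network`, `cluster`, `similarity`
#' @export
match_clusters_to_reference <- function(clusters, reference_maps) {
  cent <- t(vapply(clusters, function(c) c$centroid,
                   numeric(length(clusters[[1]]$centroid))))
  R <- abs(stats::cor(t(reference_maps), t(cent)))
  data.frame(network = seq_len(nrow(reference_maps)),
             cluster = apply(R, 1, which.max),
             similarity = apply(R, 1, max))
}
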