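#' Spatial similarity between component maps
#'
#' Absolute Pearson correlation over brain voxels. The absolute value
#' makes the measure invariant to the arbitrary sign of an ICA component.
#'
#' @param map_a,map_b numeric vectors over the same mask
#' @return similarity in [0, 1]
#' @export
spatial_similarity <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("spatial_similarity: maps are on different masks")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("spatial_similarity: zero-variance map")
  abs(stats::cor(map_a, map_b))
}

# Exact linear assignment (Jonker-Volgenant style shortest augmenting
# paths with potentials). `cost` square; returns p with p[i] = column
# assigned to row i, minimising total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)        # row potentials, index r+1 (row 0 = dummy)
  v <- numeric(n + 1)        # column potentials, index c+1 (col 0 = dummy)
  p <- integer(n + 1)        # p[c+1] = row matched to column c (0 = none)
  way <- integer(n + 1)
  cols <- 2:(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      cur <- cost[i0, ] - u[i0 + 1] - v[cols]
      upd <- !used[cols] & cur < minv[cols]
      if (any(upd)) {
        minv[cols][upd] <- cur[upd]
        way[cols][upd] <- j0
      }
      free <- which(!used[cols])
      j1 <- free[which.min(minv[free + 1])]
      delta <- minv[j1 + 1]
      adj <- used
      u[p[adj] + 1] <- u[p[adj] + 1] + delta
      v[adj] <- v[adj] - delta
      minv[!adj] <- minv[!adj] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  out[p[cols]] <- seq_len(n)
  out
}

new_component_cluster <- function(label, members, member_maps) {
  structure(list(label = label, members = members,
                 member_maps = member_maps, centroid = NULL),
            class = "component_cluster")
}

#' Cluster matched components across component sets
#'
#' Constraint-respecting clustering with exactly one member per set:
#' clusters are seeded with the first set's K components; each further
#' set's components are matched to the current cluster centroids by an
#' exact one-to-one assignment maximising summed absolute spatial
#' correlation, and centroids (sign-aligned, z-scored mean member maps)
#' are updated after each set. Sets are processed in sorted
#' (subject, day, timepoint) order, so the result does not depend on the
#' order in which sets are supplied; cluster labels follow the first
#' set's component indices.
#'
#' @param sets list of `component_set` objects sharing K and mask
#' @return list of K `component_cluster` objects; each holds a `members`
#'   data.frame (subject, day, timepoint, index), the aligned
#'   `member_maps` matrix (one row per set) and the final `centroid`
#' @export
cluster_sets <- function(sets) {
  if (length(sets) < 1) stop("cluster_sets: need at least one set")
  K <- sets[[1]]$K
  V <- ncol(sets[[1]]$maps)
  for (s in sets) {
    if (s$K != K) stop("cluster_sets: sets have unequal K")
    if (ncol(s$maps) != V) stop("cluster_sets: sets are on different masks")
  }
  ord <- order(vapply(sets, function(s)
    paste(s$subject, s$day, s$timepoint), character(1)))
  sets <- sets[ord]

  members <- lapply(seq_len(K), function(k)
    data.frame(subject = sets[[1]]$subject, day = sets[[1]]$day,
               timepoint = sets[[1]]$timepoint, index = k))
  member_maps <- lapply(seq_len(K), function(k)
    sets[[1]]$maps[k, , drop = FALSE])
  centroids <- sets[[1]]$maps

  for (si in seq_along(sets)[-1]) {
    s <- sets[[si]]
    R <- abs(stats::cor(t(centroids), t(s$maps)))   # K clusters x K comps
    assign <- solve_assignment(1 - R)               # maximise similarity
    for (k in seq_len(K)) {
      comp <- assign[k]
      m <- s$maps[comp, ]
      if (stats::cor(centroids[k, ], m) < 0) m <- -m
      members[[k]] <- rbind(members[[k]],
                            data.frame(subject = s$subject, day = s$day,
                                       timepoint = s$timepoint, index = comp))
      member_maps[[k]] <- rbind(member_maps[[k]], m)
      centroids[k, ] <- zscale_map(colMeans(member_maps[[k]]))
    }
  }
  lapply(seq_len(K), function(k) {
    cl <- new_component_cluster(k, members[[k]], member_maps[[k]])
    cl$centroid <- centroids[k, ]
    cl
  })
}

#' Mean within-cluster similarity
#'
#' Mean pairwise absolute spatial correlation among a cluster's member
#' maps (1 for a singleton cluster).
#'
#' @param cluster a `component_cluster`
#' @return similarity in [0, 1]
#' @export
within_cluster_similarity <- function(cluster) {
  n <- nrow(cluster$member_maps)
  if (n < 2) return(1)
  R <- abs(stats::cor(t(cluster$member_maps)))
  mean(R[upper.tri(R)])
}

#' Two-level hierarchical grouping from baseline scans
#'
#' Level 1 clusters, within each subject, the components of the two
#' baseline scans (FD-T1 and WD-T1) and averages each matched pair into
#' one representative map per cluster (z-scored mean, sign-aligned),
#' yielding one representative component set per subject; a subject with a
#' single baseline set passes through unchanged. Level 2 clusters the
#' representative sets across subjects into K group clusters with exactly
#' one member per subject. Only T1 sets are consulted: any set from
#' another time point is rejected, so exhausted-state scans cannot bias
#' the group templates.
#'
#' @param sets list of `component_set` objects, all with timepoint "T1"
#' @return list with `clusters` (K `component_cluster`s, members one per
#'   subject), `representatives` (per-subject representative sets) and
#'   `level1` (per-subject baseline pair clusterings, NULL for
#'   passthrough subjects)
#' @export
hierarchical_group <- function(sets) {
  if (any(vapply(sets, function(s) s$timepoint, character(1)) != "T1"))
    stop("hierarchical_group: only baseline (T1) component sets may enter")
  subjects <- sort(unique(vapply(sets, function(s) s$subject, character(1))))
  if (length(subjects) < 2) stop("hierarchical_group: need >= 2 subjects")
  K <- sets[[1]]$K

  level1 <- list()
  representatives <- list()
  for (sub in subjects) {
    mine <- Filter(function(s) s$subject == sub, sets)
    if (length(mine) == 1L) {
      rep_maps <- mine[[1]]$maps
      level1[[sub]] <- NULL
    } else {
      cl <- cluster_sets(mine)
      rep_maps <- t(vapply(cl, function(c)
        zscale_map(colMeans(c$member_maps)), numeric(ncol(mine[[1]]$maps))))
      level1[[sub]] <- cl
    }
    representatives[[sub]] <- structure(
      list(subject = sub, day = "T1-pooled", timepoint = "T1", K = K,
           maps = rep_maps, courses = NULL),
      class = "component_set")
  }
  clusters <- cluster_sets(representatives)
  list(clusters = clusters, representatives = representatives,
       level1 = level1)
}
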