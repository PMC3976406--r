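test_that("spatial similarity is |r| with its identity and sign properties", {
  set.seed(1)
  m <- rnorm(500)
  expect_equal(spatial_similarity(m, m), 1)
  expect_equal(spatial_similarity(m, -m), 1)
  expect_error(spatial_similarity(m, rep(0, 500)), "zero-variance")
  # two independent noise maps at V = 1000 are nearly orthogonal
  sims <- vapply(1:50, function(i) {
    set.seed(i)
    spatial_similarity(rnorm(1000), rnorm(1000))
  }, numeric(1))
  expect_lt(stats::median(sims), 0.1)
  expect_lt(mean(sims >= 0.1), 0.1)
})

test_that("the assignment solver equals exhaustive enumeration on small instances", {
  all_perms <- function(n) {
    out <- NULL
    rec <- function(pre, rest) {
      if (!length(rest)) out <<- rbind(out, pre)
      else for (r in rest) rec(c(pre, r), setdiff(rest, r))
    }
    rec(integer(0), seq_len(n))
    out
  }
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    C <- matrix(runif(n * n), n, n)
    got <- rsnica:::solve_assignment(C)
    costs <- apply(all_perms(n), 1, function(p) sum(C[cbind(1:n, p)]))
    expect_equal(sum(C[cbind(1:n, got)]), min(costs), tolerance = 1e-12)
  }
})

test_that("greedy set clustering equals exhaustive assignment on tiny instances", {
  # 3 sets x 3 components: enumerate all 6^2 ways of matching sets 2 and 3
  # to set 1 and compare total centroid similarity with cluster_sets
  all_perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1))
  set.seed(11)
  for (rep in 1:5) {
    maps1 <- t(apply(matrix(rnorm(3 * 200), 3), 1, zscale_map))
    jitter <- function(m) t(apply(m + 0.3 * matrix(rnorm(length(m)),
                                                   nrow(m)), 1, zscale_map))
    sets <- list(fake_set(maps1, "s1"), fake_set(jitter(maps1), "s2"),
                 fake_set(jitter(maps1), "s3"))
    got <- cluster_sets(sets)
    got_sim <- mean(vapply(got, within_cluster_similarity, numeric(1)))
    best <- -Inf
    for (i in 1:6) for (j in 1:6) {
      p2 <- all_perms3[i, ]; p3 <- all_perms3[j, ]
      val <- mean(vapply(1:3, function(k) {
        M <- rbind(sets[[1]]$maps[k, ], sets[[2]]$maps[p2[k], ],
                   sets[[3]]$maps[p3[k], ])
        R <- abs(stats::cor(t(M)))
        mean(R[upper.tri(R)])
      }, numeric(1)))
      best <- max(best, val)
    }
    expect_equal(got_sim, best, tolerance = 1e-10)
  }
})

test_that("clustering reunites identical maps under planted permutations", {
  set.seed(3)
  base <- t(apply(matrix(rnorm(5 * 300), 5), 1, zscale_map))
  perms <- list(c(3, 1, 5, 2, 4), c(5, 4, 3, 2, 1), 1:5)
  sets <- lapply(seq_along(perms), function(i)
    fake_set(base[perms[[i]], ], sprintf("s%02d", i)))
  cl <- cluster_sets(sets)
  expect_length(cl, 5)
  for (k in 1:5) {
    expect_equal(nrow(cl[[k]]$members), 3)
    expect_equal(within_cluster_similarity(cl[[k]]), 1, tolerance = 1e-10)
    # every member resolves back to the same underlying map as the first
    # set's component k (cluster labels follow the first set)
    target <- perms[[1]][k]
    expect_true(all(vapply(seq_along(perms), function(i) {
      idx <- cl[[k]]$members$index[cl[[k]]$members$subject ==
                                     sprintf("s%02d", i)]
      perms[[i]][idx] == target
    }, logical(1))))
  }
})

test_that("clustering is invariant to the order sets are supplied in", {
  sets <- Filter(function(s) s$timepoint == "T1", small_study_sets())
  cl1 <- cluster_sets(sets)
  cl2 <- cluster_sets(rev(sets))
  for (k in seq_along(cl1)) {
    expect_identical(cl1[[k]]$members, cl2[[k]]$members)
    expect_equal(cl1[[k]]$centroid, cl2[[k]]$centroid)
  }
})

test_that("sets with unequal K are rejected", {
  s1 <- fake_set(t(apply(matrix(rnorm(600), 3), 1, zscale_map)), "s1")
  s2 <- fake_set(t(apply(matrix(rnorm(400), 2), 1, zscale_map)), "s2")
  expect_error(cluster_sets(list(s1, s2)), "unequal K")
})

test_that("hierarchical grouping clusters baselines into one-per-subject groups", {
  sets <- Filter(function(s) s$timepoint == "T1", small_study_sets())
  hg <- hierarchical_group(sets)
  expect_length(hg$clusters, 6)
  for (cl in hg$clusters) {
    expect_equal(nrow(cl$members), 4)
    expect_equal(sort(cl$members$subject), sprintf("s%02d", 1:4))
  }
  # the planted networks come out as tight clusters
  st <- small_study()
  m <- match_clusters_to_reference(hg$clusters, st$truth$atlas$maps)
  ws <- vapply(m$cluster, function(ci)
    within_cluster_similarity(hg$clusters[[ci]]), numeric(1))
  expect_gt(mean(ws), 0.8)
})

test_that("level one is the identity for single-baseline subjects", {
  sets <- Filter(function(s) s$timepoint == "T1" & s$day == "FD",
                 small_study_sets())
  hg <- hierarchical_group(sets)
  expect_true(all(vapply(hg$level1, is.null, logical(1))) ||
                length(hg$level1) == 0)
  for (sub in names(hg$representatives)) {
    orig <- sets[[which(vapply(sets, function(s) s$subject == sub,
                               logical(1)))]]
    expect_identical(hg$representatives[[sub]]$maps, orig$maps)
  }
})

test_that("non-baseline sets are refused by construction", {
  sets <- small_study_sets()
  expect_error(hierarchical_group(sets), "only baseline")
})

test_that("stronger between-subject jitter never tightens clusters", {
  # seeded grid of jitter magnitudes; mean within-cluster similarity of
  # the truth-matched clusters must be non-increasing
  atlas <- small_atlas()
  sim_at <- function(shift_max) {
    st <- simulate_group_study(n_subjects = 3, atlas = atlas, n_vol = 64,
                               subject_shift_max = shift_max, seed = 9)
    t1 <- grep("-T1$", names(st$scans), value = TRUE)
    sets <- lapply(seq_along(t1), function(i) {
      sim <- st$scans[[t1[i]]]
      decompose_scan(preprocess_scan(sim$scan, sim$confounds), K = 5,
                     seed = 400 + i)
    })
    hg <- hierarchical_group(sets)
    m <- match_clusters_to_reference(hg$clusters, atlas$maps)
    mean(vapply(m$cluster, function(ci)
      within_cluster_similarity(hg$clusters[[ci]]), numeric(1)))
  }
  sims <- vapply(c(0, 1, 3), sim_at, numeric(1))
  expect_true(all(diff(sims) <= 0.02))  # non-increasing up to estimation noise
})
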