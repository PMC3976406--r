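study_contrast <- contrast_spec()

test_that("contrast specifications are validated", {
  expect_error(contrast_spec(c("A" = 1, "B" = -0.5)), "sum to 0")
  expect_error(contrast_spec(c(1, -1)), "named")
  sp <- contrast_spec()
  expect_equal(sum(sp$weights), 0)
  expect_equal(unname(sp$weights["WD-T3"]), 3)
})

test_that("the contrast t-map matches a full design-matrix GLM oracle", {
  # within-subject contrast t == t of the contrast estimate in an OLS with
  # explicit subject effects, computed from scratch at each voxel
  set.seed(1)
  n <- 8
  conds <- c("WD-T3", "WD-T1", "FD-T1", "FD-T3")
  V <- 12
  maps <- lapply(conds, function(c) matrix(rnorm(n * V), n, V,
                                           dimnames = list(sprintf("s%d", 1:n))))
  names(maps) <- conds
  tm <- contrast_tmap(maps, study_contrast)
  expect_identical(tm$df, 7L)

  w <- c(3, -1, -1, -1)
  for (v in c(1, 5, 12)) {
    y <- unlist(lapply(conds, function(c) maps[[c]][, v]))
    cond_f <- factor(rep(conds, each = n), levels = conds)
    subj_f <- factor(rep(1:n, times = 4))
    X <- stats::model.matrix(~ 0 + cond_f + subj_f)
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    cvec <- c(w, rep(0, n - 1))
    est <- sum(cvec * beta)
    c_s <- 3 * maps[["WD-T3"]][, v] - maps[["WD-T1"]][, v] -
      maps[["FD-T1"]][, v] - maps[["FD-T3"]][, v]
    # the GLM contrast estimate equals the mean contrast score exactly
    expect_equal(est, mean(c_s), tolerance = 1e-8)
    # one-sample t on the scores, through the independent lm machinery
    t_lm <- summary(stats::lm(c_s ~ 1))$coefficients[1, "t value"]
    expect_equal(tm$values[v], t_lm, tolerance = 1e-8)
  }
})

test_that("the contrast is invariant to subject-specific constant maps", {
  set.seed(2)
  n <- 6; V <- 30
  conds <- names(study_contrast$weights)
  maps <- lapply(conds, function(c) matrix(rnorm(n * V), n, V))
  names(maps) <- conds
  t0 <- contrast_tmap(maps, study_contrast)$values
  offset <- matrix(rnorm(n), n, V)   # per-subject constant across conditions
  shifted <- lapply(maps, function(m) m + offset)
  t1 <- contrast_tmap(shifted, study_contrast)$values
  expect_equal(t0, t1, tolerance = 1e-8)
})

test_that("noiseless uniform shifts hit the zero-variance cap with factor 3", {
  n <- 5; V <- 4
  base <- matrix(rnorm(n * V), n, V)
  delta <- 0.3
  maps <- list("WD-T3" = base + delta, "WD-T1" = base, "FD-T1" = base,
               "FD-T3" = base)
  tm <- contrast_tmap(maps, study_contrast)
  # c_s = 3 * delta for every subject: zero variance, capped positive
  expect_true(all(tm$values == 1e6))
  expect_equal(tm$n_capped, V)
  expect_equal(colMeans(attr(tm, "scores")), rep(3 * delta, V),
               tolerance = 1e-12)
  # all conditions identical: t = 0 everywhere
  tm0 <- contrast_tmap(list("WD-T3" = base, "WD-T1" = base, "FD-T1" = base,
                            "FD-T3" = base), study_contrast)
  expect_true(all(tm0$values == 0))
})

test_that("missing conditions fail naming the problem", {
  n <- 4; V <- 3
  maps <- list("WD-T3" = matrix(rnorm(n * V), n, V))
  expect_error(contrast_tmap(maps, study_contrast), "missing condition")
})

test_that("smoothness estimates track the generating kernel", {
  grid <- study_grid()
  # white noise: close to the voxel size
  ests <- vapply(1:20, function(s) {
    v <- with(list(), { set.seed(s); rnorm(grid$n_voxels) })
    estimate_smoothness(v, grid)
  }, numeric(1))
  expect_lt(abs(mean(ests) - grid$voxel_size_mm) / grid$voxel_size_mm, 0.2)

  # 6 mm smoothing: within 20% of 6 mm, and monotone in the kernel
  sm_est <- function(fwhm, s) {
    set.seed(s)
    f <- array(rnorm(prod(grid$dims)), grid$dims)
    f <- rsnica:::gaussian_smooth(f, rsnica:::fwhm_to_sd_vox(fwhm, 3))
    estimate_smoothness(f[grid$mask_idx], grid)
  }
  e6 <- vapply(1:10, function(s) sm_est(6, s), numeric(1))
  expect_lt(abs(mean(e6) - 6) / 6, 0.2)
  ladder <- vapply(c(4, 6, 9, 12), function(f)
    mean(vapply(1:5, function(s) sm_est(f, s), numeric(1))), numeric(1))
  expect_true(all(diff(ladder) > 0))
  expect_error(estimate_smoothness(rep(1, grid$n_voxels), grid), "constant")
})

test_that("Monte-Carlo cluster thresholds are monotone in alpha", {
  grid <- small_grid()
  k05 <- cluster_threshold_mc(grid, fwhm_mm = 5, alpha = 0.05,
                              n_iter = 200, seed = 1)
  k01 <- cluster_threshold_mc(grid, fwhm_mm = 5, alpha = 0.01,
                              n_iter = 200, seed = 1)
  expect_gte(as.integer(k01), as.integer(k05))
})

test_that("ACF-coloured nulls reduce to white noise and track smoothing", {
  grid <- small_grid()
  set.seed(21)
  white <- matrix(rnorm(8 * grid$n_voxels), 8)
  spec_w <- estimate_acf_spectrum(white, grid)
  k_acf <- cluster_threshold_mc(grid, 0, alpha = 0.05, n_iter = 300,
                                seed = 3, acf_spectrum = spec_w)
  k_white <- cluster_threshold_mc(grid, 0, alpha = 0.05, n_iter = 300,
                                  seed = 3)
  expect_lte(abs(as.integer(k_acf) - as.integer(k_white)), 1)

  smooth <- t(apply(white, 1, function(v)
    vol_to_smoothed(v, grid, 6)))
  spec_s <- estimate_acf_spectrum(smooth, grid)
  k_smooth <- cluster_threshold_mc(grid, 0, alpha = 0.05, n_iter = 300,
                                   seed = 3, acf_spectrum = spec_s)
  expect_gt(as.integer(k_smooth), as.integer(k_acf))
})

test_that("cluster extraction obeys connectivity and reporting rules", {
  grid <- study_grid()
  vals <- rep(0, grid$n_voxels)
  d <- grid$dims
  vol <- array(FALSE, d)
  # a 13-voxel face-connected cross centred mid-volume
  ctr <- c(12, 12, 8)
  blob <- rbind(ctr,
                ctr + c(1, 0, 0), ctr + c(2, 0, 0), ctr - c(1, 0, 0),
                ctr + c(0, 1, 0), ctr + c(0, 2, 0), ctr - c(0, 1, 0),
                ctr + c(0, 0, 1), ctr + c(0, 0, 2), ctr - c(0, 0, 1),
                ctr + c(1, 1, 0), ctr + c(1, 2, 0), ctr + c(2, 1, 0))
  lin <- blob[, 1] + (blob[, 2] - 1) * d[1] + (blob[, 3] - 1) * d[1] * d[2]
  pos <- match(lin, grid$mask_idx)
  expect_false(anyNA(pos))
  vals[pos] <- 10
  tmap <- structure(list(values = vals, df = 7L, tail = "two",
                         n_capped = 0L), class = "stat_map")
  cl <- extract_clusters(tmap, grid, voxel_p = 0.01, min_size = 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$extension_mm3, 13 * 27)
  expect_equal(cl[[1]]$sign, "enhancement")
  expect_equal(cl[[1]]$avg_t, 10)
  expect_equal(cl[[1]]$max_t, 10)
  com_vox <- colMeans(blob)   # uniform weights at equal |t|
  expect_equal(cl[[1]]$center_of_mass_mm,
               (com_vox - (d + 1) / 2) * 3, tolerance = 1e-10,
               ignore_attr = TRUE)

  # two voxels touching only diagonally form two clusters
  vals2 <- rep(0, grid$n_voxels)
  lin2 <- c(ctr, ctr + c(1, 1, 0)) # two corner-touching voxels
  l2 <- c(ctr[1] + (ctr[2] - 1) * d[1] + (ctr[3] - 1) * d[1] * d[2],
          ctr[1] + 1 + ctr[2] * d[1] + (ctr[3] - 1) * d[1] * d[2])
  vals2[match(l2, grid$mask_idx)] <- c(8, -8)
  tmap2 <- structure(list(values = vals2, df = 7L, tail = "two",
                          n_capped = 0L), class = "stat_map")
  cl2 <- extract_clusters(tmap2, grid, voxel_p = 0.01, min_size = 1)
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, function(c) c$sign, character(1)),
                  c("enhancement", "suppression"))
  # min_size drops small clusters
  expect_length(extract_clusters(tmap2, grid, voxel_p = 0.01,
                                 min_size = 2), 0)
})

test_that("regional scores are plain means over the region", {
  set.seed(5)
  maps <- list(list(subject = "s1", condition = "WD-T3", map = rnorm(100)),
               list(subject = "s2", condition = "WD-T3", map = rnorm(100)))
  reg <- c(4L, 10L, 50L)
  sc <- regional_scores(maps, reg)
  expect_equal(sc$score[1], mean(maps[[1]]$map[reg]))
  expect_equal(sc$score[2], mean(maps[[2]]$map[reg]))
  one <- regional_scores(maps, 7L)
  expect_equal(one$score[1], maps[[1]]$map[7])
  cmap <- maps; cmap[[1]]$map[] <- 3.3
  expect_equal(regional_scores(cmap, reg)$score[1], 3.3)
})

test_that("the ANCOVA partial F matches a nested-RSS oracle", {
  set.seed(6)
  tab <- data.frame(subject = rep(sprintf("s%d", 1:6), 2),
                    scan = rep(c("WD-T2", "WD-T3"), each = 6),
                    vas = runif(12, 20, 120))
  tab$score <- 0.5 + 0.01 * tab$vas + 0.2 * (tab$scan == "WD-T3") +
    rnorm(12, 0, 0.1)
  got <- ancova_scores(tab)

  rss <- function(form) sum(stats::residuals(stats::lm(form, tab))^2)
  r0 <- rss(score ~ scan); r1 <- rss(score ~ scan + vas)
  r2 <- rss(score ~ scan * vas)
  f_vas <- ((r0 - r1) / 1) / (r1 / 9)
  f_int <- ((r1 - r2) / 1) / (r2 / 8)
  expect_equal(unname(got$vas["F"]), f_vas, tolerance = 1e-8)
  expect_equal(unname(got$interaction["F"]), f_int, tolerance = 1e-8)
  expect_equal(unname(got$vas["p"]),
               stats::pf(f_vas, 1, 9, lower.tail = FALSE), tolerance = 1e-10)

  # exact linear dependence: huge covariate F, near-zero interaction F
  tab2 <- tab
  tab2$score <- 1 + 0.02 * tab2$vas
  got2 <- ancova_scores(tab2)
  expect_gt(unname(got2$vas["F"]), 1e10)
  expect_lt(unname(got2$interaction["F"]), 1e-6)
})

test_that("the ANCOVA null covariate p-value is calibrated", {
  # b = 0: empirical rejection at 0.05 should sit near 0.05
  set.seed(7)
  rej <- vapply(1:500, function(i) {
    tab <- data.frame(subject = rep(sprintf("s%d", 1:8), 2),
                      scan = rep(c("WD-T2", "WD-T3"), each = 8),
                      vas = runif(16, 20, 120),
                      score = rnorm(16))
    ancova_scores(tab)$vas["p"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
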