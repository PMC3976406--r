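test_that("atlas construction is deterministic and respects core disjointness", {
  grid <- study_grid()
  a1 <- make_atlas(grid, 7, seed = 9)
  a2 <- make_atlas(grid, 7, seed = 9)
  expect_identical(a1$maps, a2$maps)
  expect_identical(a1$core_masks, a2$core_masks)

  # 7 networks x 2 cores: every pair of cores is disjoint
  expect_lte(max(colSums(a1$core_masks)), 1)
  for (k in seq_len(7))
    expect_true(all(a1$supports[k, a1$core_masks[k, ]]))
})

test_that("unsmoothed atlas maps equal their blob indicators", {
  a <- make_atlas(small_grid(), 3, fwhm_mm = 0, seed = 4)
  expect_true(all(a$maps %in% c(0, 1)))
  expect_identical(a$maps > 0, a$core_masks)
})

test_that("atlas placement fails loudly when cores cannot fit", {
  g <- volume_grid(c(6, 6, 6), brain_mask = array(TRUE, c(6, 6, 6)))
  expect_error(make_atlas(g, 10, core_radius_mm = 9),
               "too small to place")
})

test_that("network time courses are band-limited to 0.01-0.1 Hz", {
  for (n_vol in c(120, 180)) {
    s <- band_limited_course(n_vol, tr_s = 2, seed = 3)
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(stats::sd(s), 1, tolerance = 1e-12)
    pw <- Mod(stats::fft(s))^2
    j <- 0:(n_vol - 1)
    freqs <- pmin(j, n_vol - j) / (n_vol * 2)   # fold to [0, Nyquist]
    in_band <- freqs >= 0.01 - 1e-9 & freqs <= 0.1 + 1e-9
    expect_gte(sum(pw[in_band]) / sum(pw[-1]), 0.99)
  }
})

test_that("noise-free scans are exact superpositions of map x course", {
  a <- make_atlas(small_grid(), 2, fwhm_mm = 0, seed = 4)
  one_net <- a
  one_net$maps[2, ] <- 0   # silence the second network
  sim <- simulate_scan(one_net, list(), "FD-T1", n_vol = 64, noise_sd = 0,
                       drift_amp = 0, physio_amp = 0, seed = 6)
  expected <- sim$truth$courses[, 1] %*% t(one_net$maps[1, ])
  expect_equal(sim$scan$data, expected + sim$truth$courses[, 2] %*%
                 t(one_net$maps[2, ] * 0), tolerance = 1e-12)
})

test_that("a planted gain scales regional temporal SD by exactly that factor", {
  a <- make_atlas(small_grid(), 3, fwhm_mm = 0, seed = 4)
  core <- which(a$core_masks[1, ])
  region <- core[seq_len(floor(length(core) / 2))]
  ef <- effect_spec(1, region, c("WD-T3" = 1.5), atlas = a)
  sim <- simulate_scan(a, list(ef), "WD-T3", n_vol = 64, noise_sd = 0,
                       drift_amp = 0, physio_amp = 0, seed = 6)
  sds <- apply(sim$scan$data, 2, stats::sd)
  same_weight_outside <- setdiff(core, region)
  expect_equal(mean(sds[region]) / mean(sds[same_weight_outside]), 1.5,
               tolerance = 1e-10)
  # outside the target region amplitudes are condition-invariant
  sim0 <- simulate_scan(a, list(ef), "FD-T1", n_vol = 64, noise_sd = 0,
                        drift_amp = 0, physio_amp = 0, seed = 6)
  sds0 <- apply(sim0$scan$data, 2, stats::sd)
  expect_equal(sds[same_weight_outside], sds0[same_weight_outside],
               tolerance = 1e-10)
})

test_that("conditions outside the design are rejected", {
  expect_error(simulate_scan(small_atlas(), list(), "FD-T2", n_vol = 64),
               "not in the design")
})

test_that("group studies are reproducible scan by scan from the master seed", {
  st <- small_study()
  expect_length(st$scans, 4 * 5)
  # every (subject, condition) rebuilds bit-exactly from the same seed
  resim <- simulate_group_study(n_subjects = 4, atlas = small_atlas(),
                                n_vol = 96, seed = 42)
  pick <- c("s01_FD-T1", "s03_WD-T3")
  for (nm in pick)
    expect_identical(st$scans[[nm]]$scan$data, resim$scans[[nm]]$scan$data)
})

test_that("a study without effects is marked null and label-exchangeable", {
  st0 <- simulate_group_study(n_subjects = 3, atlas = small_atlas(),
                              n_vol = 64, noise_sd = 0, seed = 5,
                              simulate_scans = FALSE)
  expect_true(st0$truth$null_study)
  expect_true(all(st0$truth$modulation == 0))

  # condition labels enter the generative model only through the planted
  # gains: without effects, two scans differing only in their label are
  # bit-identical given the same seed, and with an effect they differ
  # exclusively inside the target region
  a <- small_atlas()
  base <- simulate_scan(a, list(), "FD-T1", n_vol = 64, seed = 9)
  relab <- simulate_scan(a, list(), "WD-T3", n_vol = 64, seed = 9)
  expect_identical(base$scan$data, relab$scan$data)

  region <- which(a$core_masks[1, ])
  ef <- effect_spec(1, region, c("WD-T3" = 1.5), atlas = a)
  with_ef <- simulate_scan(a, list(ef), "WD-T3", n_vol = 64, seed = 9)
  changed <- which(colSums(abs(with_ef$scan$data - base$scan$data)) > 1e-10)
  expect_true(all(changed %in% region))
})

test_that("planted gain schedules order regional amplitudes monotonically", {
  a <- small_atlas()
  core <- which(a$core_masks[1, ])
  ef <- effect_spec(1, core, c("WD-T2" = 1.25, "WD-T3" = 1.5), atlas = a)
  st <- simulate_group_study(n_subjects = 3, atlas = a, effects = list(ef),
                             n_vol = 64, seed = 8)
  amp <- st$truth$amplitudes
  reg <- tapply(amp$regional_amplitude[amp$network == 1],
                amp$condition[amp$network == 1], mean)
  expect_lt(mean(reg[c("WD-T1", "FD-T1", "FD-T3")]), reg["WD-T2"])
  expect_lt(reg["WD-T2"], reg["WD-T3"])
})

test_that("behavioural scores couple to the planted modulation", {
  st <- small_study()   # no effects: modulation flat
  expect_true(all(st$truth$modulation == 0))
  a <- small_atlas()
  ef <- effect_spec(1, which(a$core_masks[1, ]), c("WD-T3" = 1.5), atlas = a)
  # rank correlation between pooled exhaustion and planted modulation is
  # positive in nearly all seeds at default coupling
  hits <- 0
  for (seed in 1:20) {
    st1 <- simulate_group_study(n_subjects = 4, atlas = a,
                                effects = list(ef), n_vol = 32, seed = seed,
                                simulate_scans = FALSE)
    beh <- st1$behavior
    beh$pooled <- pool_vas(beh$tired_vas, beh$rested_vas)
    rho <- stats::cor(beh$pooled, st1$truth$modulation[beh$condition],
                      method = "spearman")
    hits <- hits + (rho > 0)
  }
  expect_gte(hits, 19)
})
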