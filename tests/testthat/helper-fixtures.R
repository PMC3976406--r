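# lazily built, cached fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_grid <- function() fixture("small_grid", function()
  volume_grid(c(16, 16, 12)))

study_grid <- function() fixture("study_grid", function()
  volume_grid(c(24, 24, 16)))

small_atlas <- function() fixture("small_atlas", function()
  make_atlas(small_grid(), 3, seed = 2))

# one preprocessed small scan with 3 planted networks (moderate length so
# ICA is quick); used by decomposition and templating tests
small_scan <- function() fixture("small_scan", function() {
  sim <- simulate_scan(small_atlas(), list(), "FD-T1", n_vol = 96, seed = 7)
  preprocess_scan(sim$scan, sim$confounds)
})

small_components <- function() fixture("small_components", function()
  decompose_scan(small_scan(), K = 6, seed = 5))

# 20 seeded replicates of planted-source recovery: for each replicate a
# fresh 3-network scan is decomposed and each network's best-matching
# component (by |spatial correlation|) recorded, together with the
# component chosen by goodness-of-fit against the network support.
recovery_replicates <- function() fixture("recovery_replicates", function() {
  atlas <- small_atlas()
  grid <- small_grid()
  lapply(1:20, function(seed) {
    sim <- simulate_scan(atlas, list(), "FD-T1", n_vol = 96,
                         seed = 1000 + seed)
    cs <- decompose_scan(preprocess_scan(sim$scan, sim$confounds),
                         K = 6, seed = seed)
    R <- abs(stats::cor(t(atlas$maps), t(cs$maps)))
    list(set = cs,
         best_r = apply(R, 1, max),
         best_comp = apply(R, 1, which.max))
  })
})

# a small complete study (4 subjects, 3 networks) for grouping tests
small_study <- function() fixture("small_study", function()
  simulate_group_study(n_subjects = 4, atlas = small_atlas(),
                       n_vol = 96, seed = 42))

small_study_sets <- function() fixture("small_study_sets", function() {
  st <- small_study()
  sets <- lapply(seq_along(st$scans), function(i) {
    sim <- st$scans[[i]]
    decompose_scan(preprocess_scan(sim$scan, sim$confounds), K = 6,
                   seed = 300 + i)
  })
  names(sets) <- names(st$scans)
  sets
})

# smooth a mask-vector map with a Gaussian kernel of the given FWHM (mm)
vol_to_smoothed <- function(v, grid, fwhm_mm) {
  a <- rsnica:::gaussian_smooth(rsnica:::vec_to_vol(v, grid),
                                rsnica:::fwhm_to_sd_vox(fwhm_mm,
                                                        grid$voxel_size_mm))
  a[grid$mask_idx]
}

# a component set built directly from given maps
fake_set <- function(maps, subject, day = "FD", timepoint = "T1") {
  structure(list(subject = subject, day = day, timepoint = timepoint,
                 condition = paste0(day, "-", timepoint),
                 K = nrow(maps), maps = maps, courses = NULL),
            class = "component_set")
}

# independently coded two-way ANOVA sums-of-squares oracle (balanced)
anova2_oracle <- function(y, f1, f2) {
  n <- length(y)
  gm <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  n1 <- table(f1)[1]
  n2 <- table(f2)[1]
  ncell <- table(interaction(f1, f2))[1]
  ss1 <- sum(n1 * (m1 - gm)^2)
  ss2 <- sum(n2 * (m2 - gm)^2)
  sscell <- sum(ncell * (m12 - gm)^2)
  ss12 <- sscell - ss1 - ss2
  sstot <- sum((y - gm)^2)
  sse <- sstot - sscell
  dfe <- n - length(m12)
  list(F1 = (ss1 / (length(m1) - 1)) / (sse / dfe),
       F2 = (ss2 / (length(m2) - 1)) / (sse / dfe),
       F12 = (ss12 / ((length(m1) - 1) * (length(m2) - 1))) / (sse / dfe),
       dfe = dfe, mse = sse / dfe)
}
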