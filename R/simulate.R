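#' Study design labels
#'
#' The repeated-measures design: every subject is scanned five times, at
#' three time points (T1 morning, T2 mid, T3 late afternoon) on a work day
#' (WD) and at T1/T3 on a free day (FD). Templates are later built from the
#' two baseline (T1) scans only.
#'
#' @return character vector of the five scan condition labels
#' @export
rsn_conditions <- function() c("FD-T1", "FD-T3", "WD-T1", "WD-T2", "WD-T3")

condition_day <- function(cond) sub("-.*$", "", cond)
condition_timepoint <- function(cond) sub("^.*-", "", cond)

#' Band-limited network time course
#'
#' White Gaussian noise restricted by FFT to the resting-state band
#' (0.01-0.1 Hz by default), rescaled to zero mean and unit SD.
#'
#' @param n_vol number of volumes (>= 32)
#' @param tr_s repetition time in seconds
#' @param band frequency band in Hz
#' @param seed integer seed
#' @return numeric vector of length `n_vol`
#' @export
band_limited_course <- function(n_vol, tr_s, band = c(0.01, 0.1), seed = 1L) {
  if (n_vol < 32) stop("band_limited_course: n_vol must be >= 32")
  freqs <- seq_len(floor(n_vol / 2)) / (n_vol * tr_s)
  keep <- which(freqs >= band[1] & freqs <= band[2])
  if (length(keep) == 0L)
    stop("band_limited_course: no Fourier bin falls inside the band")
  x <- with_seed(seed, stats::rnorm(n_vol))
  xf <- stats::fft(x)
  sel <- rep(FALSE, n_vol)
  sel[keep + 1L] <- TRUE                  # positive frequencies
  sel[n_vol - keep + 1L] <- TRUE          # conjugate bins
  xf[!sel] <- 0
  s <- Re(stats::fft(xf, inverse = TRUE)) / n_vol
  (s - mean(s)) / stats::sd(s)
}

#' Simulate a single resting-state scan
#'
#' The scan is built as
#' `data = sum_k a_k * gain_k(voxel, condition) * map_k * s_k(t) + drift +
#' physio + noise`, where `s_k` is a band-limited (0.01-0.1 Hz) network
#' time course, the gain differs from 1 only inside an effect's target
#' region and only for conditions named in its `condition_gains`, drift is
#' a low-order polynomial with smooth spatial coefficient fields, and the
#' physiological term mixes cardiac and respiratory sinusoids (sampled at
#' TR, hence aliased) through smooth spatial weight maps. The confound
#' phases are returned exactly as mixed in.
#'
#' @param atlas a [make_atlas()] atlas
#' @param effects list of [effect_spec()] objects
#' @param condition scan label; must be one of [rsn_conditions()]
#' @param tr_s repetition time in s (default 2)
#' @param n_vol number of volumes (default 180, >= 32)
#' @param noise_sd SD of additive white Gaussian noise (default 0.02,
#'   relative to unit network amplitude)
#' @param amplitudes optional per-network amplitude vector (default all 1)
#' @param drift_amp SD of the polynomial drift coefficient fields (default 0.1)
#' @param physio_amp SD of the physiological spatial weight fields (default 0.1)
#' @param cardiac_hz,resp_hz cardiac and respiratory frequencies (defaults
#'   1.05 and 0.27 Hz; at TR 2 s the cardiac line aliases to 0.05 Hz, inside
#'   the network band, which is what nuisance regression must remove)
#' @param subject subject id recorded on the scan (default "s1")
#' @param seed integer seed; the scan is deterministic given all arguments
#' @return list with `scan` (class `rsn_scan`: subject/day/timepoint/tr_s,
#'   `data` T x V matrix over in-mask voxels, `grid`), `confounds` (class
#'   `confound_set`: `motion` T x 6, `cardiac_phase`, `resp_phase`), and
#'   `truth` (network courses, amplitudes, per-voxel gain fields)
#' @export
simulate_scan <- function(atlas, effects = list(), condition,
                          tr_s = 2, n_vol = 180, noise_sd = 0.02,
                          amplitudes = NULL, drift_amp = 0.1,
                          physio_amp = 0.1, cardiac_hz = 1.05, resp_hz = 0.27,
                          subject = "s1", seed = 1L) {
  stopifnot(inherits(atlas, "network_atlas"))
  if (!condition %in% rsn_conditions())
    stop(sprintf("simulate_scan: condition '%s' is not in the design (%s)",
                 condition, paste(rsn_conditions(), collapse = ", ")))
  if (n_vol < 32) stop("simulate_scan: n_vol must be >= 32")
  if (noise_sd < 0) stop("simulate_scan: noise_sd must be >= 0")
  grid <- atlas$grid
  V <- grid$n_voxels
  K <- nrow(atlas$maps)
  if (is.null(amplitudes)) amplitudes <- rep(1, K)
  stopifnot(length(amplitudes) == K)

  # condition-dependent per-voxel gain field per network
  gains <- matrix(1, K, V)
  for (ef in effects) {
    g <- ef$condition_gains[condition]
    if (!is.na(g) && g != 1)
      gains[ef$target_network, ef$target_region] <-
        gains[ef$target_network, ef$target_region] * g
  }

  courses <- vapply(seq_len(K), function(k)
    band_limited_course(n_vol, tr_s, seed = sub_seed(seed, k)),
    numeric(n_vol))                       # T x K
  eff_maps <- sweep(atlas$maps * gains, 1, amplitudes, "*")   # K x V
  data <- courses %*% eff_maps            # T x V

  t01 <- seq(-1, 1, length.out = n_vol)
  smooth_field <- function(s, amp) {
    f <- with_seed(s, array(stats::rnorm(prod(grid$dims)), grid$dims))
    f <- gaussian_smooth(f, 1.5)
    v <- vol_to_vec(f, grid)
    amp * v / stats::sd(v)
  }
  if (drift_amp > 0) {
    data <- data + cbind(t01, t01^2 - mean(t01^2)) %*%
      rbind(smooth_field(sub_seed(seed, 101), drift_amp),
            smooth_field(sub_seed(seed, 102), drift_amp))
  }
  tt <- (seq_len(n_vol) - 1) * tr_s
  cardiac_phase <- (2 * pi * cardiac_hz * tt) %% (2 * pi)
  resp_phase <- (2 * pi * resp_hz * tt) %% (2 * pi)
  if (physio_amp > 0) {
    P <- cbind(cos(cardiac_phase), sin(cardiac_phase),
               cos(resp_phase), sin(resp_phase))
    W <- rbind(smooth_field(sub_seed(seed, 111), physio_amp),
               smooth_field(sub_seed(seed, 112), physio_amp),
               smooth_field(sub_seed(seed, 113), physio_amp),
               smooth_field(sub_seed(seed, 114), physio_amp))
    data <- data + P %*% W
  }
  if (noise_sd > 0)
    data <- data + with_seed(sub_seed(seed, 999),
                             matrix(stats::rnorm(n_vol * V, sd = noise_sd),
                                    n_vol, V))
  motion <- with_seed(sub_seed(seed, 121),
                      apply(matrix(stats::rnorm(n_vol * 6, sd = 0.02),
                                   n_vol, 6), 2, cumsum))
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")

  scan <- structure(
    list(subject = subject, day = condition_day(condition),
         timepoint = condition_timepoint(condition), condition = condition,
         tr_s = tr_s, data = data, grid = grid),
    class = "rsn_scan")
  confounds <- structure(
    list(motion = motion, cardiac_phase = cardiac_phase,
         resp_phase = resp_phase),
    class = "confound_set")
  truth <- list(courses = courses, amplitudes = amplitudes, gains = gains,
                condition = condition, seed = seed)
  list(scan = scan, confounds = confounds, truth = truth)
}

#' @export
print.rsn_scan <- function(x, ...) {
  cat(sprintf("<rsn_scan> %s %s: %d vols x %d voxels, TR %g s\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

# deterministic per-scan seed within a study
scan_seed <- function(seed, subject_no, condition)
  sub_seed(seed, 10000 + subject_no * 10 + match(condition, rsn_conditions()))

#' Simulate a full repeated-measures group study
#'
#' Generates `n_subjects` subjects x five scan conditions with a shared
#' group atlas. Each subject's atlas is the group atlas under a seeded
#' sub-voxel rigid shift of at most one voxel in norm (effect regions
#' shift with it), and each scan draws its network amplitudes from a
#' lognormal perturbation
#' around 1. Behavioural exhaustion scores are coupled linearly to the
#' planted modulation magnitude of each condition, so behaviour-score
#' correlations are recoverable downstream.
#'
#' @param n_subjects number of subjects (>= 3)
#' @param atlas group atlas; built with defaults when NULL
#' @param grid grid used when `atlas` is NULL
#' @param n_networks networks when `atlas` is NULL (default 5)
#' @param effects list of [effect_spec()] (possibly empty: a null study)
#' @param tr_s,n_vol,noise_sd per-scan parameters, see [simulate_scan()]
#' @param subject_shift_max bound on the subject rigid shift in voxels
#'   (per-axis uniform on +/- half this value; default 1)
#' @param amp_jitter_sd SD of the per-scan log-amplitude jitter (default 0.1)
#' @param vas_baseline,vas_slope,vas_noise_sd behavioural coupling: pooled
#'   exhaustion ~ baseline + subject offset + slope * mean|gain - 1| + noise
#'   (defaults 40, 100, 8 on the 0-150 VAS scale)
#' @param seed integer master seed; every scan is reproducible from
#'   (seed, subject, condition) alone
#' @param simulate_scans generate the imaging data (default TRUE); FALSE
#'   produces only the behavioural table and ground truth, which is much
#'   faster when the imaging stages are not needed
#' @param conditions which scan conditions to materialise (default all
#'   five); the behavioural table and truth always cover the full design.
#'   Per-scan seeds depend only on (seed, subject, condition), so a
#'   restricted study reproduces the corresponding scans of the full one
#' @return object of class `rsn_study`: `scans` (named list of
#'   [simulate_scan()] results, names "s<i>_<condition>"), `behavior`
#'   (data.frame subject/day/timepoint/condition/tired_vas/rested_vas),
#'   `truth` (atlas, per-subject shifts, effects, amplitude realisations,
#'   modulation schedule, coupling parameters, `null_study` flag)
#' @export
simulate_group_study <- function(n_subjects = 8, atlas = NULL, grid = NULL,
                                 n_networks = 5, effects = list(),
                                 tr_s = 2, n_vol = 180, noise_sd = 0.02,
                                 subject_shift_max = 1L, amp_jitter_sd = 0.1,
                                 vas_baseline = 40, vas_slope = 100,
                                 vas_noise_sd = 8, seed = 1L,
                                 simulate_scans = TRUE,
                                 conditions = rsn_conditions()) {
  if (n_subjects < 3) stop("simulate_group_study: need >= 3 subjects")
  if (is.null(atlas)) {
    if (is.null(grid)) grid <- volume_grid(c(24, 24, 16))
    atlas <- make_atlas(grid, n_networks, seed = sub_seed(seed, 1))
  }
  grid <- atlas$grid
  K <- nrow(atlas$maps)
  conds <- rsn_conditions()

  # per-condition planted modulation magnitude (drives behaviour coupling)
  modulation <- vapply(conds, function(cond) {
    if (length(effects) == 0L) return(0)
    mean(vapply(effects, function(ef) {
      g <- ef$condition_gains[cond]
      if (is.na(g)) 0 else abs(g - 1)
    }, numeric(1)))
  }, numeric(1))

  subjects <- sprintf("s%02d", seq_len(n_subjects))
  # continuous sub-voxel rigid shifts, per-axis uniform in
  # [-shift_max/2, shift_max/2] (Euclidean norm <= shift_max voxels)
  shifts <- t(vapply(seq_len(n_subjects), function(s)
    with_seed(sub_seed(seed, 200 + s),
              stats::runif(3, -subject_shift_max / 2, subject_shift_max / 2)),
    numeric(3)))

  scans <- list()
  amp_rows <- list()
  beh_rows <- list()
  for (s in seq_len(n_subjects)) {
    if (simulate_scans) {
      sub_atlas <- shift_atlas(atlas, shifts[s, ],
                               with_masks = length(effects) > 0)
      sub_effects <- lapply(effects, function(ef)
        shift_effect(ef, sub_atlas, shifts[s, ]))
    }
    vas_offset <- with_seed(sub_seed(seed, 300 + s), stats::rnorm(1, 0, 10))
    for (cond in conds) {
      sseed <- scan_seed(seed, s, cond)
      amps <- with_seed(sub_seed(sseed, 7),
                        exp(stats::rnorm(K, 0, amp_jitter_sd)))
      if (simulate_scans && cond %in% conditions)
        scans[[paste0(subjects[s], "_", cond)]] <-
          simulate_scan(sub_atlas, sub_effects, cond, tr_s = tr_s,
                        n_vol = n_vol, noise_sd = noise_sd,
                        amplitudes = amps, subject = subjects[s],
                        seed = sseed)
      amp_rows[[length(amp_rows) + 1L]] <-
        data.frame(subject = subjects[s], condition = cond,
                   network = seq_len(K), amplitude = amps,
                   regional_amplitude = amps * vapply(seq_len(K), function(k)
                     regional_gain(effects, k, cond), numeric(1)))
      pooled <- vas_baseline + vas_offset + vas_slope * modulation[cond] +
        with_seed(sub_seed(sseed, 8), stats::rnorm(1, 0, vas_noise_sd))
      pooled <- min(max(pooled, 0), 150)
      jit <- with_seed(sub_seed(sseed, 9), stats::rnorm(2, 0, 3))
      beh_rows[[length(beh_rows) + 1L]] <-
        data.frame(subject = subjects[s], day = condition_day(cond),
                   timepoint = condition_timepoint(cond), condition = cond,
                   tired_vas = min(max(pooled + jit[1], 0), 150),
                   rested_vas = min(max(150 - pooled + jit[2], 0), 150))
    }
  }
  behavior <- do.call(rbind, beh_rows)
  rownames(behavior) <- NULL
  truth <- list(atlas = atlas, effects = effects, shifts = shifts,
                subjects = subjects,
                amplitudes = do.call(rbind, amp_rows),
                modulation = modulation,
                coupling = list(baseline = vas_baseline, slope = vas_slope,
                                noise_sd = vas_noise_sd),
                null_study = all(modulation == 0), seed = seed)
  structure(list(scans = scans, behavior = behavior, truth = truth,
                 grid = grid),
            class = "rsn_study")
}

# condition gain of network k combined over effects (1 when none applies)
regional_gain <- function(effects, k, cond) {
  g <- 1
  for (ef in effects)
    if (ef$target_network == k && !is.na(ef$condition_gains[cond]))
      g <- g * unname(ef$condition_gains[cond])
  g
}

# rigid (possibly sub-voxel) shift of the atlas; cores/supports are only
# shifted when needed (i.e. when planted effects must follow the subject)
shift_atlas <- function(atlas, shift, with_masks = TRUE) {
  if (all(shift == 0)) return(atlas)
  grid <- atlas$grid
  shifted <- atlas
  for (k in seq_len(nrow(atlas$maps))) {
    shifted$maps[k, ] <- vol_to_vec(
      shift_array(vec_to_vol(atlas$maps[k, ], grid), shift), grid)
    if (with_masks) {
      shifted$core_masks[k, ] <- vol_to_vec(
        shift_array(vec_to_vol(atlas$core_masks[k, ], grid), shift),
        grid) >= 0.5
      shifted$supports[k, ] <- vol_to_vec(
        shift_array(vec_to_vol(atlas$supports[k, ], grid), shift), grid) > 0
    }
  }
  # keep the containment invariant after edge clipping
  if (with_masks) shifted$supports <- shifted$supports | shifted$core_masks
  shifted
}

# the effect region follows the subject's shifted atlas; voxels with
# majority interpolated weight form the shifted region, clipped to the
# shifted support to preserve the containment invariant
shift_effect <- function(ef, shifted_atlas, shift) {
  if (all(shift == 0)) return(ef)
  grid <- shifted_atlas$grid
  reg <- numeric(grid$n_voxels)
  reg[ef$target_region] <- 1
  reg <- vol_to_vec(shift_array(vec_to_vol(reg, grid), shift), grid) >= 0.5
  reg <- reg & shifted_atlas$supports[ef$target_network, ]
  out <- ef
  out$target_region <- which(reg)
  out
}

# integer shift with zero fill
shift_array_int <- function(a, shift) {
  d <- dim(a)
  out <- array(0, d)
  src <- lapply(1:3, function(i) {
    s <- shift[i]
    (max(1, 1 - s)):(min(d[i], d[i] - s))
  })
  dst <- lapply(1:3, function(i) src[[i]] + shift[i])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# rigid shift by a real-valued offset: trilinear combination of the eight
# neighbouring integer shifts
shift_array <- function(a, shift) {
  if (all(shift == round(shift)))
    return(shift_array_int(a, as.integer(round(shift))))
  lo <- floor(shift)
  fr <- shift - lo
  out <- array(0, dim(a))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
    if (w > 0)
      out <- out + w * shift_array_int(a, as.integer(lo + c(cx, cy, cz)))
  }
  out
}

#' @export
print.rsn_study <- function(x, ...) {
  cat(sprintf("<rsn_study> %d subjects x %d scans, %d networks%s\n",
              length(x$truth$subjects),
              length(x$scans) / length(x$truth$subjects),
              nrow(x$truth$atlas$maps),
              if (x$truth$null_study) " (null study)" else ""))
  invisible(x)
}
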