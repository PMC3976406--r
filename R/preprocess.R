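#' Discrete-cosine drift basis
#'
#' Basis function k has frequency k / (2 T tr) Hz, i.e. k/2 cycles per
#' time-course, so a cutoff of `c` cycles per course corresponds to
#' functions k = 1..floor(2c).
#'
#' @param n_vol number of time points
#' @param n_funcs number of cosine functions (excluding the constant)
#' @return `n_vol` x `n_funcs` matrix
#' @keywords internal
dct_basis <- function(n_vol, n_funcs) {
  t <- seq_len(n_vol) - 0.5
  vapply(seq_len(n_funcs), function(k) cos(pi * k * t / n_vol),
         numeric(n_vol))
}

#' Temporal high-pass filter by drift-basis projection
#'
#' Projects out, per voxel, the constant plus a discrete-cosine basis
#' spanning all frequencies at or below `cutoff_cycles` cycles per
#' time-course (i.e. `cutoff_cycles / (T tr)` Hz). Being a linear
#' projection the filter is idempotent and leaves each voxel with zero
#' mean.
#'
#' @param scan an `rsn_scan`
#' @param cutoff_cycles cutoff in cycles per time-course (default 2)
#' @return filtered `rsn_scan`
#' @export
highpass <- function(scan, cutoff_cycles = 2) {
  stopifnot(inherits(scan, "rsn_scan"))
  if (cutoff_cycles < 0) stop("highpass: cutoff_cycles must be >= 0")
  T <- nrow(scan$data)
  n_basis <- floor(2 * cutoff_cycles)
  if (n_basis + 1 >= T)
    stop("highpass: cutoff implies as many basis functions as time points")
  X <- cbind(1, if (n_basis > 0) dct_basis(T, n_basis))
  scan$data <- scan$data - X %*% solve(crossprod(X), crossprod(X, scan$data))
  attr(scan, "preproc") <- c(attr(scan, "preproc"),
                             sprintf("highpass(%g cycles)", cutoff_cycles))
  scan
}

#' RETROICOR-style physiological regressors
#'
#' Fourier expansion of the cardiac and respiratory phase series up to the
#' given harmonic order. Column order is fixed and documented: all cardiac
#' columns first, then respiratory; within a modality, harmonics ascend
#' with cosine before sine (`card_cos1, card_sin1, card_cos2, card_sin2,
#' resp_cos1, ...`).
#'
#' @param cardiac_phase,resp_phase phase series in radians, equal length
#' @param order harmonic order (default 2), giving `4 * order` columns
#' @return T x (4 * order) matrix with named columns
#' @export
build_physio_regressors <- function(cardiac_phase, resp_phase, order = 2) {
  if (order < 1) stop("build_physio_regressors: order must be >= 1")
  if (length(cardiac_phase) != length(resp_phase))
    stop("build_physio_regressors: phase series lengths differ")
  one <- function(phase, tag) {
    cols <- lapply(seq_len(order), function(m)
      cbind(cos(m * phase), sin(m * phase)))
    out <- do.call(cbind, cols)
    colnames(out) <- as.vector(vapply(seq_len(order), function(m)
      paste0(tag, c("_cos", "_sin"), m), character(2)))
    out
  }
  cbind(one(cardiac_phase, "card"), one(resp_phase, "resp"))
}

#' Nuisance regression by GLM residualisation
#'
#' Fits, per voxel, an ordinary least-squares model on an intercept plus
#' the supplied confound columns and keeps the residuals, which are then
#' orthogonal to every confound column.
#'
#' @param scan an `rsn_scan`
#' @param confounds T x p numeric matrix (p < T); must be full column rank
#'   together with the intercept
#' @return residualised `rsn_scan`
#' @export
regress_confounds <- function(scan, confounds) {
  stopifnot(inherits(scan, "rsn_scan"))
  confounds <- as.matrix(confounds)
  T <- nrow(scan$data)
  if (nrow(confounds) != T)
    stop("regress_confounds: confound rows must match scan volumes")
  if (ncol(confounds) >= T)
    stop("regress_confounds: more confounds than time points")
  X <- cbind(intercept = 1, confounds)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    if (is.null(bad)) bad <- q$pivot[(q$rank + 1):ncol(X)]
    stop(sprintf("regress_confounds: rank-deficient design; offending columns: %s",
                 paste(bad, collapse = ", ")))
  }
  scan$data <- scan$data - X %*% solve(crossprod(X), crossprod(X, scan$data))
  attr(scan, "preproc") <- c(attr(scan, "preproc"),
                             sprintf("regress_confounds(p=%d)", ncol(confounds)))
  scan
}

#' Motion-based scan exclusion
#'
#' A scan is excluded when the largest absolute translation along any axis
#' strictly exceeds `limit_mm` (4 mm by default). Rotations are reported
#' but do not gate.
#'
#' @param motion T x 6 matrix: 3 translations (mm) then 3 rotations (deg)
#' @param limit_mm translation limit in mm (default 4, strict `>`)
#' @return list with `verdict` ("keep"/"exclude"), `max_translation_mm`,
#'   `max_rotation_deg`
#' @export
motion_qc <- function(motion, limit_mm = 4) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion_qc: motion must have 6 columns")
  mt <- max(abs(motion[, 1:3]))
  mr <- max(abs(motion[, 4:6]))
  list(verdict = if (mt > limit_mm) "exclude" else "keep",
       max_translation_mm = mt, max_rotation_deg = mr)
}

#' Standard preprocessing for one scan
#'
#' Fixed pipeline order: temporal high-pass, then nuisance regression on
#' motion parameters plus RETROICOR regressors. The applied steps are
#' logged on the scan's `preproc` attribute.
#'
#' @param scan an `rsn_scan`
#' @param confounds a `confound_set` from [simulate_scan()] (or a list with
#'   `motion`, `cardiac_phase`, `resp_phase`)
#' @param hp_cycles high-pass cutoff in cycles per time-course (default 2)
#' @param physio_order RETROICOR harmonic order (default 2)
#' @return preprocessed `rsn_scan`
#' @export
preprocess_scan <- function(scan, confounds, hp_cycles = 2, physio_order = 2) {
  scan <- highpass(scan, hp_cycles)
  X <- cbind(confounds$motion,
             build_physio_regressors(confounds$cardiac_phase,
                                     confounds$resp_phase, physio_order))
  regress_confounds(scan, X)
}
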