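#' Component-count rule
#'
#' Smallest component count that is at least one `divisor`-th of the
#' number of time points: `ceiling(T / divisor)`. With the default divisor
#' 6, a 180-volume scan yields 30 components.
#'
#' @param n_vol number of time points T (>= divisor)
#' @param divisor rule divisor (default 6)
#' @return integer component count
#' @export
select_component_count <- function(n_vol, divisor = 6) {
  if (n_vol < divisor)
    stop("select_component_count: fewer time points than the divisor")
  as.integer(ceiling(n_vol / divisor))
}

#' Scale a spatial map to z-scores
#'
#' Subtracts the mean and divides by the sample SD computed over brain
#' (mask) voxels, so the result expresses each voxel's weight in standard
#' deviations of the map's spatial distribution.
#'
#' @param raw_map numeric vector over mask voxels
#' @return z-scored vector (mean 0, SD 1)
#' @export
zscale_map <- function(raw_map) {
  s <- stats::sd(raw_map)
  if (!is.finite(s) || s == 0)
    stop("zscale_map: map has zero spatial variance")
  (raw_map - mean(raw_map)) / s
}

map_skewness <- function(x) {
  xc <- x - mean(x)
  mean(xc^3) / (mean(xc^2)^1.5)
}

# Symmetric FastICA (tanh contrast) on whitened K x V data. The usual
# max-delta stopping rule (largest change in any component direction
# cosine) is dominated by near-Gaussian components whose direction is
# statistically indifferent and wobbles at O(1/sqrt(V)); strongly
# non-Gaussian source components settle orders of magnitude tighter. So:
# stop at `tol` when reached, otherwise keep the most stable iterate seen
# and accept it if its delta is below `accept_tol`; return NULL (caller
# restarts) only beyond that.
fastica_core <- function(Z, seed, max_iter = 200, tol = 1e-4,
                         accept_tol = 0.5) {
  K <- nrow(Z)
  V <- ncol(Z)
  sym_orth <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*%
      t(e$vectors) %*% W
  }
  W <- sym_orth(with_seed(seed, matrix(stats::rnorm(K * K), K, K)))
  best <- list(W = W, iters = 0L, delta = Inf, strict = FALSE)
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Z)
    W_new <- sym_orth(tcrossprod(G, Z) / V - rowMeans(1 - G^2) * W)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < best$delta)
      best <- list(W = W, iters = it, delta = delta, strict = FALSE)
    if (delta < tol) {
      best$strict <- TRUE
      return(best)
    }
  }
  if (best$delta < accept_tol) best else NULL
}

#' Per-scan PCA-reduced spatial ICA
#'
#' Reduces the (voxel-demeaned) time x voxel matrix to its `K` leading
#' principal components, whitens the spatial modes, and unmixes them with
#' a symmetric fixed-point FastICA (tanh contrast). Each resulting spatial
#' map is z-scored over brain voxels and sign-flipped to nonnegative
#' skewness; components are ordered by descending explained variance. The
#' decomposition is deterministic given the seed; on non-convergence up to
#' `restarts` further seeded initialisations are tried before failing.
#'
#' @param scan a preprocessed `rsn_scan`
#' @param K number of components; defaults to the
#'   [select_component_count()] rule
#' @param seed integer seed for the ICA initialisation
#' @param max_iter fixed-point iteration cap per restart (default 200)
#' @param restarts additional seeded initialisations on non-convergence
#'   (default 5)
#' @return object of class `component_set`: `subject`, `day`, `timepoint`,
#'   `condition`, `K`, `maps` (K x V z-scored), `courses` (T x K),
#'   `var_retained` (fraction of total variance captured by the K
#'   principal components), `explained` (per-component variance share),
#'   `seed`, `iters`
#' @export
decompose_scan <- function(scan, K = NULL, seed = 1L, max_iter = 200,
                           restarts = 5) {
  stopifnot(inherits(scan, "rsn_scan"))
  T <- nrow(scan$data)
  if (is.null(K)) K <- select_component_count(T)
  if (K > T) stop("decompose_scan: K must not exceed the number of volumes")
  X <- scan$data
  X <- sweep(X, 2, colMeans(X))

  # temporal eigendecomposition (T x T) gives the PCA cheaply
  C <- tcrossprod(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  var_retained <- sum(ev[seq_len(K)]) / sum(ev)
  U <- e$vectors[, seq_len(K), drop = FALSE]
  P <- crossprod(X, U)                        # V x K orthogonal spatial modes

  # center spatial modes over voxels and re-whiten (K x K problem)
  P <- sweep(P, 2, colMeans(P))
  ew <- eigen(crossprod(P) / nrow(P), symmetric = TRUE)
  wh <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-12)), K) %*%
    t(ew$vectors)
  Z <- t(P %*% wh)                            # K x V whitened

  fit <- NULL
  for (r in 0:restarts) {
    fit <- fastica_core(Z, seed = sub_seed(seed, r), max_iter = max_iter)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf(paste0("decompose_scan: FastICA did not converge in %d ",
                        "iterations after %d restarts (K=%d, T=%d)"),
                 max_iter, restarts, K, T))
  S <- fit$W %*% Z                            # K x V sources, unit variance

  # time courses by least squares of the data on the source maps
  A <- X %*% t(S) %*% solve(tcrossprod(S))    # T x K

  # sign convention (nonnegative spatial skewness), z-scoring, ordering
  maps <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    m <- S[k, ]
    if (map_skewness(m) < 0) {
      m <- -m
      A[, k] <- -A[, k]
    }
    maps[k, ] <- zscale_map(m)
  }
  explained <- colSums(A^2) * rowSums(S^2)
  explained <- explained / sum(explained)
  ord <- order(explained, decreasing = TRUE)

  structure(
    list(subject = scan$subject, day = scan$day, timepoint = scan$timepoint,
         condition = scan$condition, K = K,
         maps = maps[ord, , drop = FALSE],
         courses = A[, ord, drop = FALSE],
         var_retained = var_retained, explained = explained[ord],
         seed = seed, iters = fit$iters, delta = fit$delta,
         strict_convergence = fit$strict),
    class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %s %s: K=%d, var retained %.2f%%\n",
              x$subject, x$condition, x$K, 100 * x$var_retained))
  invisible(x)
}
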