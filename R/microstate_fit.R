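#' Global field power
#'
#' The spatial (across-channel) standard deviation of the potential vector at
#' each sample. Peaks of GFP mark moments of maximal topographic
#' signal-to-noise, where microstate maps are estimated.
#'
#' @param rec An [eeg_recording()] (should be average-referenced).
#' @return A `gfp_series` object: list with `values` (microvolts, one per
#'   sample) and `fs`.
#' @export
compute_gfp <- function(rec) {
  mu <- colMeans(rec$data)
  v <- colMeans(rec$data^2) - mu^2
  structure(list(values = sqrt(pmax(v, 0)), fs = rec$fs),
            class = "gfp_series")
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP series, with plateaus counted once at their
#' centre, thinned so that retained peaks are at least `min_distance_ms`
#' apart (higher peaks win).
#'
#' @param gfp A `gfp_series` from [compute_gfp()], or a numeric vector (then
#'   `fs` must be given).
#' @param min_distance_ms Minimum distance between retained peaks (ms).
#' @param fs Sampling rate, required when `gfp` is a bare vector.
#' @return Sorted integer vector of peak sample indices.
#' @export
find_gfp_peaks <- function(gfp, min_distance_ms = 10, fs = NULL) {
  if (inherits(gfp, "gfp_series")) {
    x <- gfp$values; fs <- gfp$fs
  } else {
    x <- as.numeric(gfp)
    if (is.null(fs)) stop("fs is required when gfp is a plain vector")
  }
  n <- length(x)
  if (n < 3) stop("series too short for peak detection")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  cand <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
        cand <- c(cand, floor((starts[i] + ends[i]) / 2))
    }
  }
  if (length(cand) == 0) stop("no GFP peaks found (degenerate input)")
  min_d <- max(1, round(min_distance_ms / 1000 * fs))
  keep <- logical(length(cand))
  taken <- integer(0)
  for (i in order(x[cand], decreasing = TRUE)) {
    if (all(abs(cand[i] - taken) >= min_d)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sort(cand[keep])
}

#' Modified k-means microstate clustering
#'
#' Fits `n_classes` unit-norm topographies to the supplied GFP-peak maps by
#' the polarity-invariant modified k-means: samples are assigned to the class
#' with maximal squared projection, and each class map is updated as the
#' dominant eigenvector of the scatter matrix of its assigned samples, which
#' minimizes the residual cost
#' `F = sum_t ||V_t - a_kt Gamma_k||^2 / (N_T (N_S - 1))` with
#' `a_kt = Gamma_k' V_t`. The procedure restarts `n_init` times from random
#' peak samples and returns the restart with the lowest predictive
#' cross-validation criterion
#' `CV = sigma2 * ((N_S - 1) / (N_S - 1 - N_K))^2`.
#'
#' @param peak_maps Samples x channels matrix of potentials at GFP peaks.
#' @param n_classes Number of microstate classes K.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum iterations per restart.
#' @param tol Relative cost-change convergence tolerance.
#' @param seed Integer seed; restart r uses the substream `seed + r - 1`.
#' @return A `microstate_solution`: list with `maps` (K x N_S unit-norm),
#'   `assignments`, `intensities`, `cost_F`, `cv`, `gev`, `n_init`, `seed`.
#' @export
modified_kmeans <- function(peak_maps, n_classes, n_init = 100,
                            max_iter = 300, tol = 1e-6, seed = NULL) {
  X <- as.matrix(peak_maps)
  Tn <- nrow(X); N <- ncol(X); K <- n_classes
  if (Tn <= K) stop("need more samples than classes")
  if (N <= K + 1) stop("need N_S > n_classes + 1 for the CV criterion")
  vn2 <- rowSums(X^2)
  denom <- Tn * (N - 1)
  if (is.null(seed)) seed <- floor(stats::runif(1, 0, 2^30))
  best <- NULL
  for (r in seq_len(n_init)) {
    sol <- with_seed_(seed + r - 1,
                      kmeans_once(X, K, vn2, denom, max_iter, tol))
    if (is.null(best) || sol$cv < best$cv) best <- sol
  }
  maps <- t(apply(best$maps, 1, fix_sign))
  colnames(maps) <- colnames(X)
  a <- (X %*% t(maps))[cbind(seq_len(Tn), best$assign)]
  structure(list(maps = maps, assignments = best$assign, intensities = a,
                 cost_F = best$cost, cv = best$cv,
                 gev = gev_compute(X, maps, best$assign),
                 n_init = n_init, seed = seed),
            class = "microstate_solution")
}

kmeans_once <- function(X, K, vn2, denom, max_iter, tol) {
  Tn <- nrow(X); N <- ncol(X)
  maps <- unit_rows(X[sample.int(Tn, K), , drop = FALSE])
  cost_prev <- Inf; assign <- NULL; cost <- NA_real_
  for (it in seq_len(max_iter)) {
    P <- X %*% t(maps)
    assign <- max.col(P^2, ties.method = "first")
    empty <- setdiff(seq_len(K), unique(assign))
    if (length(empty)) {      # re-seed empty clusters from random samples
      for (k in empty)
        maps[k, ] <- unit_rows(X[sample.int(Tn, 1), , drop = FALSE])
      P <- X %*% t(maps)
      assign <- max.col(P^2, ties.method = "first")
    }
    a <- P[cbind(seq_len(Tn), assign)]
    cost <- (sum(vn2) - sum(a^2)) / denom
    if (is.finite(cost_prev) &&
        abs(cost_prev - cost) <= tol * max(cost_prev, .Machine$double.eps))
      break
    cost_prev <- cost
    for (k in seq_len(K)) {
      idx <- which(assign == k)
      S <- crossprod(X[idx, , drop = FALSE])
      maps[k, ] <- eigen(S, symmetric = TRUE)$vectors[, 1]
    }
  }
  if (it == max_iter)
    warning("modified k-means did not converge in ", max_iter,
            " iterations; returning best iterate")
  list(maps = maps, assign = assign, cost = cost,
       cv = cv_compute(X, maps, assign))
}

cv_compute <- function(X, maps, assign) {
  N <- ncol(X); K <- nrow(maps)
  if (K >= N - 1) stop("CV is ill-posed when n_classes >= N_S - 1")
  a <- (X %*% t(maps))[cbind(seq_len(nrow(X)), assign)]
  sigma2 <- (sum(rowSums(X^2)) - sum(a^2)) / (nrow(X) * (N - 1))
  sigma2 * ((N - 1) / (N - 1 - K))^2
}

gev_compute <- function(X, maps, assign) {
  gfp <- apply(X, 1, function(v) sqrt(mean(v^2) - mean(v)^2))
  tot <- sum(gfp^2)
  if (tot <= 0) stop("zero total GFP: degenerate input")
  cr <- vapply(seq_len(nrow(X)),
               function(t) stats::cor(X[t, ], maps[assign[t], ]), numeric(1))
  sum(gfp^2 * cr^2) / tot
}

#' Cross-validation criterion of a fitted solution
#'
#' Evaluates the predictive residual-variance criterion used to compare
#' microstate clusterings on the given data.
#'
#' @param solution A `microstate_solution`, or a list with `maps` and
#'   `assignments`.
#' @param peak_maps The samples x channels matrix the solution was fitted on.
#' @return The CV value (microvolts squared).
#' @export
cross_validation <- function(solution, peak_maps) {
  cv_compute(as.matrix(peak_maps), solution$maps, solution$assignments)
}

#' Global explained variance
#'
#' Fraction of GFP-weighted topographic variance explained by the assigned
#' maps: `GEV = sum_t GFP_t^2 corr(V_t, Gamma_k(t))^2 / sum_t GFP_t^2`.
#'
#' @inheritParams cross_validation
#' @return GEV as a fraction in \[0, 1\].
#' @export
global_explained_variance <- function(solution, peak_maps) {
  gev_compute(as.matrix(peak_maps), solution$maps, solution$assignments)
}

#' @export
print.microstate_solution <- function(x, ...) {
  cat(sprintf("<microstate_solution> K = %d, cost_F = %.4g, CV = %.4g, GEV = %.3f (%d restarts)\n",
              nrow(x$maps), x$cost_F, x$cv, x$gev, x$n_init))
  invisible(x)
}
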