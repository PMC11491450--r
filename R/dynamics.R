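#' Finite entropy-rate estimate of a label sequence
#'
#' Short-range temporal dependency measure: block Shannon entropies `H(k)` of
#' the empirical k-gram distributions (Grassberger bias-corrected by default)
#' are computed for k = 1..k_max, and the entropy rate is the least-squares
#' slope of `H(k)` versus k. A constant sequence has rate 0; an i.i.d.
#' uniform K-class sequence has rate `log2(K)` bits/sample. The alternative
#' `"difference"` estimator returns `H(k_max + 1) - H(k_max)`.
#'
#' @param seq A [label_sequence()] or integer vector of labels.
#' @param k_max Largest block length used in the slope fit.
#' @param method `"slope"` (default) or `"difference"`.
#' @param correction Block-entropy bias correction: `"grassberger"`
#'   (default), `"miller-madow"`, or `"none"` (plugin).
#' @return Entropy rate in bits/sample.
#' @export
entropy_rate <- function(seq, k_max = 6, method = c("slope", "difference"),
                         correction = c("grassberger", "miller-madow",
                                        "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  x <- if (inherits(seq, "label_sequence")) seq$labels else as.integer(seq)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty sequence")
  K <- max(x)
  if (length(x) < 10 * K^k_max)
    warning("sequence shorter than the recommended 10 * K^k_max samples; ",
            "block entropies at large k may be biased")
  ks <- seq_len(if (method == "difference") k_max + 1 else k_max)
  H <- vapply(ks, function(k) block_entropy(x, k, K, correction), numeric(1))
  if (method == "difference") return(H[k_max + 1] - H[k_max])
  unname(stats::coef(stats::lm(H ~ ks))[2])
}

block_entropy <- function(x, k, K, correction = "grassberger") {
  n <- length(x) - k + 1
  code <- numeric(n)
  for (i in 0:(k - 1)) code <- code + (x[(1 + i):(n + i)] - 1) * K^i
  cnt <- as.numeric(table(code))
  p <- cnt / n
  switch(correction,
         none = -sum(p * log2(p)),
         `miller-madow` = -sum(p * log2(p)) +
           (length(cnt) - 1) / (2 * n * log(2)),
         grassberger = {
           G <- digamma(cnt) + 0.5 * (-1)^cnt *
             (digamma((cnt + 1) / 2) - digamma(cnt / 2))
           (log(n) - sum(cnt * G) / n) / log(2)
         })
}

#' Enumerate balanced bipartitions of the classes
#'
#' All unordered splits of the K classes into a subset of size `floor(K/2)`
#' (mapped to +1) and its complement (mapped to -1), each {subset,
#' complement} pair counted once, in lexicographic order. For 7 classes this
#' gives the 35 three-versus-four partitions used for the Hurst analysis.
#'
#' @param n_classes Number of classes (>= 2).
#' @return List of integer vectors: the class indices mapped to +1.
#' @export
enumerate_partitions <- function(n_classes) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  m <- floor(n_classes / 2)
  subsets <- utils::combn(n_classes, m, simplify = FALSE)
  if (n_classes %% 2 == 0)   # complement pairs appear twice: keep those with class 1
    subsets <- Filter(function(s) 1 %in% s, subsets)
  subsets
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' DFA of a +/-1 (or any numeric) sequence: the profile is the cumulative sum
#' of the mean-centred sequence; for each window size the RMS residual of a
#' least-squares polynomial detrend (default linear) is computed over
#' half-overlapping windows, and the Hurst exponent is the slope of
#' `log F(n)` against `log n`. 0.5 indicates an uncorrelated sequence,
#' larger values persistence.
#'
#' @param x Numeric sequence (length >= 500).
#' @param window_sizes Integer window sizes; default ~18 log-spaced sizes
#'   from 10 to n/4.
#' @param order Detrending polynomial order.
#' @param n_sizes Number of log-spaced window sizes when `window_sizes` is
#'   `NULL`.
#' @return The Hurst estimate, with attributes `window_sizes` and
#'   `fluctuations`.
#' @export
dfa_hurst <- function(x, window_sizes = NULL, order = 1, n_sizes = 18) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 500) stop("sequence too short for DFA (need >= 500 samples)")
  if (max(x) == min(x)) stop("constant sequence: DFA undefined")
  if (is.null(window_sizes))
    window_sizes <- unique(round(exp(seq(log(10), log(n / 4),
                                         length.out = n_sizes))))
  window_sizes <- sort(unique(as.integer(window_sizes)))
  window_sizes <- window_sizes[window_sizes >= order + 2 & window_sizes <= n]
  if (length(window_sizes) < 3) stop("need at least 3 usable window sizes")
  Y <- cumsum(x - mean(x))
  Fw <- vapply(window_sizes, function(w) {
    starts <- seq(1L, n - w + 1L, by = max(1L, w %/% 2L))
    idx <- outer(seq_len(w) - 1L, starts, "+")
    D <- stats::poly(seq_len(w), degree = order, raw = TRUE)
    R <- qr.resid(qr(cbind(1, D)), matrix(Y[idx], w, length(starts)))
    sqrt(mean(colMeans(R^2)))
  }, numeric(1))
  h <- unname(stats::coef(stats::lm(log(Fw) ~ log(window_sizes)))[2])
  structure(h, window_sizes = window_sizes, fluctuations = Fw)
}

#' Mean Hurst exponent across all class bipartitions
#'
#' Maps the label sequence to -1/+1 under every balanced bipartition from
#' [enumerate_partitions()], estimates the DFA Hurst exponent of each mapped
#' sequence, and averages. Partitions yielding a constant sequence are
#' skipped with a warning and excluded from the mean.
#'
#' @param seq A [label_sequence()] or integer label vector.
#' @param n_classes Number of classes; inferred when `seq` is a
#'   [label_sequence()].
#' @param ... Passed to [dfa_hurst()].
#' @return A `dynamics_result`: list with `hurst_per_partition`,
#'   `hurst_mean`, `partitions`, `n_skipped`.
#' @export
mean_hurst <- function(seq, n_classes = NULL, ...) {
  x <- if (inherits(seq, "label_sequence")) seq$labels else as.integer(seq)
  x <- x[!is.na(x)]
  K <- n_classes %||%
    (if (inherits(seq, "label_sequence")) seq$n_classes else max(x))
  parts <- enumerate_partitions(K)
  hs <- rep(NA_real_, length(parts))
  for (i in seq_along(parts)) {
    s <- ifelse(x %in% parts[[i]], 1, -1)
    if (max(s) == min(s)) next
    hs[i] <- as.numeric(dfa_hurst(s, ...))
  }
  if (anyNA(hs))
    warning(sum(is.na(hs)), " degenerate partition sequence(s) skipped")
  structure(list(hurst_per_partition = hs, hurst_mean = mean(hs, na.rm = TRUE),
                 partitions = parts, n_skipped = sum(is.na(hs))),
            class = "dynamics_result")
}

#' Short- and long-range temporal dependency measures
#'
#' Convenience wrapper computing both the finite entropy rate and the
#' partition-averaged DFA Hurst exponent of one label sequence.
#'
#' @param seq A [label_sequence()].
#' @param k_max Block length for [entropy_rate()].
#' @param ... Passed to [mean_hurst()] / [dfa_hurst()].
#' @return A `dynamics_result` with `entropy_rate` added.
#' @export
sequence_dynamics <- function(seq, k_max = 6, ...) {
  res <- mean_hurst(seq, ...)
  res$entropy_rate <- entropy_rate(seq, k_max = k_max)
  res
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("<dynamics_result> mean Hurst = %.3f over %d partitions%s\n",
              x$hurst_mean, length(x$hurst_per_partition),
              if (!is.null(x$entropy_rate))
                sprintf(", entropy rate = %.3f bits/sample", x$entropy_rate)
              else ""))
  invisible(x)
}
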