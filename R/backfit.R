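#' Backfit global maps onto a recording
#'
#' Assigns every sample the class whose map has the highest absolute spatial
#' correlation with the sample topography (polarity ignored). No temporal
#' smoothing of any kind is applied, so the temporal dynamics of the label
#' sequence are untouched. Zero-variance samples cannot be correlated and are
#' marked unlabeled (NA) with a warning; they are excluded from parameter
#' computation.
#'
#' @param rec An [eeg_recording()].
#' @param global_maps A `template_maps` object or K x N map matrix with the
#'   same channel set as `rec`.
#' @param meta Optional task metadata attached to the output.
#' @return A [label_sequence()] with per-sample winning |correlation|.
#' @export
backfit <- function(rec, global_maps, meta = list()) {
  M <- if (inherits(global_maps, "template_maps")) global_maps$maps
       else as.matrix(global_maps)
  if (ncol(M) != n_channels(rec))
    stop("channel sets of recording and maps differ")
  X <- rec$data
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  Mc <- M - rowMeans(M)
  sm <- sqrt(rowSums(Mc^2))
  C <- t(Mc %*% Xc) / outer(sx, sm)                # samples x K
  bad <- which(sx == 0)
  if (length(bad)) {
    warning(length(bad), " zero-variance sample(s) left unlabeled")
    C[bad, ] <- NA_real_
  }
  lab <- max.col(abs(C), ties.method = "first")
  corr <- pmin(abs(C[cbind(seq_len(nrow(C)), lab)]), 1)
  lab[bad] <- NA_integer_
  label_sequence(lab, fs = rec$fs, n_classes = nrow(M), corr = corr,
                 meta = meta)
}

#' Microstate parameters of a label sequence
#'
#' Per-class coverage (fraction of labeled time), occurrence (uninterrupted
#' appearances per second) and mean duration (ms). Boundary (first and last)
#' runs are included by default, which keeps the identity
#' `coverage = occurrence * duration / 1000` exact per class.
#'
#' @param seq A [label_sequence()].
#' @param include_boundary Include the first and last run in the duration
#'   average (`TRUE`, default) or drop them.
#' @return A data.frame with one row per class: `class`, `coverage`,
#'   `occurrence`, `duration`, `n_runs` (plus any metadata columns of `seq`).
#' @export
microstate_parameters <- function(seq, include_boundary = TRUE) {
  stopifnot(inherits(seq, "label_sequence"))
  lab <- seq$labels[!is.na(seq$labels)]
  if (length(lab) == 0) stop("no labeled samples")
  K <- seq$n_classes
  r <- rle(lab)
  total_s <- length(lab) / seq$fs
  cls <- seq_len(K)
  n_k <- vapply(cls, function(k) sum(r$lengths[r$values == k]), 0)
  runs_k <- vapply(cls, function(k) sum(r$values == k), 0)
  dur_len <- r$lengths
  dur_val <- r$values
  if (!include_boundary && length(dur_len) > 2) {
    dur_len <- dur_len[-c(1, length(dur_len))]
    dur_val <- dur_val[-c(1, length(dur_val))]
  }
  dur_k <- vapply(cls, function(k) {
    l <- dur_len[dur_val == k]
    if (length(l) == 0) NA_real_ else mean(l) * 1000 / seq$fs
  }, 0)
  out <- data.frame(class = rownames_for(K), coverage = n_k / length(lab),
                    occurrence = runs_k / total_s, duration = dur_k,
                    n_runs = as.integer(runs_k))
  for (nm in names(seq$meta)) out[[nm]] <- seq$meta[[nm]]
  out
}

rownames_for <- function(K) {
  if (K <= 26) LETTERS[seq_len(K)] else as.character(seq_len(K))
}
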