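#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc FIR band-pass applied in one forward pass with
#' group-delay compensation (linear-phase design, so the compensated output is
#' zero-phase). Edges are handled by mirror padding. The default 1-40 Hz band
#' removes slow movement artifacts and line noise while keeping the bands of
#' interest.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (0 < low < high < fs/2).
#' @param transition Transition bandwidth in Hz; default
#'   `min(max(low / 4, 2), low)` (so 1 Hz at the default band).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 40, transition = NULL) {
  fs <- rec$fs
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("need 0 < low < high < fs/2")
  transition <- transition %||% min(max(low / 4, 2), low)
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- signal::fir1(ord, c(low, high) * 2 / fs, type = "pass",
                    window = signal::hamming(ord + 1))
  d <- ord / 2
  n <- n_samples(rec)
  if (n <= d) stop("recording too short for the designed filter")
  x <- t(rec$data)                                    # samples x channels
  pad_top <- x[(d + 1):2, , drop = FALSE]             # mirror padding
  pad_bot <- x[(n - 1):(n - d), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  y <- apply(xp, 2, function(col) signal::fftfilt(b, col))
  rec$data <- t(y[(2 * d + 1):(2 * d + n), , drop = FALSE])
  rownames(rec$data) <- rec$channel_names
  rec
}

new_cleaning_report <- function() {
  structure(list(bad_channels = data.frame(channel = character(),
                                           criterion = character()),
                 rejected_epochs = data.frame(epoch = integer(),
                                              criterion = character()),
                 interpolated_local = data.frame(epoch = integer(),
                                                 channel = character()),
                 warnings = character()),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d bad channel flag(s), %d rejected epoch(s), %d local interpolation(s)\n",
              nrow(x$bad_channels), nrow(x$rejected_epochs),
              nrow(x$interpolated_local)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Detect bad channels
#'
#' Flags whole channels by three criteria: (1) flat for more than
#' `flat_seconds` (peak-to-peak below `flat_eps` over a sliding window);
#' (2) correlation with the neighbourhood below `neighbor_corr`, where the
#' neighbourhood signal is the channel's spherical-spline reconstruction from
#' the remaining channels (a weighted neighbour combination, robust to
#' topographic sign structure that defeats plain pairwise correlations);
#' (3) per-channel standard deviation more than `amp_z` standard deviations
#' from the mean across channels. Each flag names the criterion that fired.
#'
#' @param rec An [eeg_recording()] (>= 3 channels).
#' @param flat_seconds Window length for the flatness criterion (s).
#' @param neighbor_corr Correlation threshold against the neighbourhood
#'   reconstruction.
#' @param amp_z z threshold on the per-channel standard deviation.
#' @param flat_eps Peak-to-peak amplitude below which a window counts as flat.
#' @param max_corr_samples Cap on the number of (evenly spaced) samples used
#'   for the correlation criterion.
#' @return A `cleaning_report` with the `bad_channels` table filled in.
#' @export
detect_bad_channels <- function(rec, flat_seconds = 5, neighbor_corr = 0.8,
                                amp_z = 3, flat_eps = 1e-6,
                                max_corr_samples = 1000L) {
  if (n_channels(rec) < 3) stop("need >= 3 channels")
  rep_ <- new_cleaning_report()
  X <- rec$data
  n <- ncol(X)
  win <- round(flat_seconds * rec$fs)
  flagged <- list()
  if (n >= win) {
    starts <- unique(c(seq(1, n - win + 1, by = max(1, round(rec$fs / 4))),
                       n - win + 1))
    for (ch in seq_len(nrow(X))) {
      for (s in starts) {
        seg <- X[ch, s:(s + win - 1)]
        if (max(seg) - min(seg) < flat_eps) {
          flagged[[length(flagged) + 1]] <-
            data.frame(channel = rec$channel_names[ch], criterion = "flat")
          break
        }
      }
    }
  }
  if (is.null(rec$positions)) {
    rep_$warnings <- c(rep_$warnings,
                       "no sensor positions: neighbour-correlation criterion disabled")
  } else if (nrow(X) >= 5) {
    sub <- X[, unique(round(seq(1, n, length.out = min(n, max_corr_samples)))),
             drop = FALSE]
    for (ch in seq_len(nrow(X))) {
      est <- spline_interp_matrix(sub, rec$positions, ch)[ch, ]
      r <- suppressWarnings(stats::cor(sub[ch, ], est))
      if (is.na(r) || r < neighbor_corr)
        flagged[[length(flagged) + 1]] <-
          data.frame(channel = rec$channel_names[ch],
                     criterion = "low neighbor correlation")
    }
  }
  sds <- apply(X, 1, stats::sd)
  sd_of_sds <- stats::sd(sds)
  if (sd_of_sds > 0) {
    z <- abs(sds - mean(sds)) / sd_of_sds
    for (ch in which(z > amp_z))
      flagged[[length(flagged) + 1]] <-
        data.frame(channel = rec$channel_names[ch], criterion = "amplitude")
  }
  if (length(flagged))
    rep_$bad_channels <- do.call(rbind, flagged)
  rep_
}

# FASTER-style per-epoch, per-channel statistics
faster_stats <- function(epochs) {
  # epochs: list of channels x samples matrices
  grand_mean <- rowMeans(do.call(cbind, epochs))
  lapply(list(
    variance = function(e) apply(e, 1, stats::var),
    median_gradient = function(e) apply(e, 1, function(x) stats::median(abs(diff(x)))),
    amplitude_range = function(e) apply(e, 1, function(x) max(x) - min(x)),
    mean_deviation = function(e) abs(rowMeans(e) - grand_mean)
  ), function(f) t(vapply(epochs, f, numeric(nrow(epochs[[1]])))))
}

#' Segment into epochs and reject artifactual data
#'
#' Splits the recording into fixed-length epochs, interpolates local bad
#' channels within each epoch (any of the four FASTER statistics - variance,
#' median gradient, amplitude range, deviation from mean amplitude - with
#' |z| > `z_thresh` across epochs), then rejects whole epochs whose amplitude
#' exceeds `amp_uV`, or whose single-electrode log-probability across epochs,
#' or electrode-group log-probability within epochs, deviates by more than
#' `z_thresh` standard deviations. Surviving epochs are concatenated in
#' order.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Epoch length in seconds.
#' @param amp_uV Absolute amplitude rejection threshold (microvolts).
#' @param z_thresh z-score threshold for the FASTER and probability criteria.
#' @return A list with `recording` (cleaned, concatenated), `epochs` (list of
#'   kept epoch matrices) and `report` (a `cleaning_report`).
#' @export
epoch_and_clean <- function(rec, epoch_seconds = 2, amp_uV = 100,
                            z_thresh = 3) {
  len <- round(epoch_seconds * rec$fs)
  n_ep <- floor(n_samples(rec) / len)
  if (n_ep < 1) stop("recording shorter than one epoch")
  rep_ <- new_cleaning_report()
  epochs <- lapply(seq_len(n_ep), function(e)
    rec$data[, ((e - 1) * len + 1):(e * len), drop = FALSE])
  # --- local bad channels (FASTER), interpolated within-epoch
  if (n_ep >= 3) {
    stats_ <- faster_stats(epochs)
    zmats <- lapply(stats_, function(S) {
      mu <- colMeans(S); sd_ <- apply(S, 2, stats::sd)
      sd_[sd_ == 0] <- Inf
      abs(sweep(sweep(S, 2, mu), 2, sd_, "/"))
    })
    bad_local <- Reduce("|", lapply(zmats, function(z) z > z_thresh))
    if (is.null(rec$positions)) {
      if (any(bad_local))
        rep_$warnings <- c(rep_$warnings,
                           "no sensor positions: local bad channels not interpolated")
    } else {
      # interpolate only sparsely-affected epochs; artifacts spanning many
      # channels are left for segment rejection
      cap <- max(1, floor(nrow(rec$data) / 5))
      for (e in which(rowSums(bad_local) > 0)) {
        bad <- which(bad_local[e, ])
        if (length(bad) <= min(cap, nrow(rec$data) - 4)) {
          epochs[[e]] <- spline_interp_matrix(epochs[[e]], rec$positions, bad)
          rep_$interpolated_local <- rbind(
            rep_$interpolated_local,
            data.frame(epoch = e, channel = rec$channel_names[bad]))
        }
      }
    }
  }
  # --- epoch rejection: amplitude, then probability criteria
  rejected <- list()
  amp_bad <- vapply(epochs, function(e) max(abs(e)) > amp_uV, logical(1))
  for (e in which(amp_bad))
    rejected[[length(rejected) + 1]] <-
      data.frame(epoch = e, criterion = "amplitude")
  if (n_ep >= 3) {
    logp <- epoch_log_probability(epochs)            # epochs x channels
    z_chan <- scale(logp)                            # across epochs, per channel
    single_bad <- apply(z_chan, 1, function(z) any(z < -z_thresh, na.rm = TRUE))
    group <- rowMeans(logp)
    z_group <- as.numeric(scale(group))
    for (e in which(single_bad & !amp_bad))
      rejected[[length(rejected) + 1]] <-
        data.frame(epoch = e, criterion = "single-electrode probability")
    for (e in which(z_group < -z_thresh & !amp_bad & !single_bad))
      rejected[[length(rejected) + 1]] <-
        data.frame(epoch = e, criterion = "electrode-group probability")
  }
  if (length(rejected))
    rep_$rejected_epochs <- do.call(rbind, rejected)
  drop <- unique(rep_$rejected_epochs$epoch)
  keep <- setdiff(seq_len(n_ep), drop)
  if (length(keep) == 0) stop("all epochs rejected: data quality too low")
  out <- rec
  out$data <- do.call(cbind, epochs[keep])
  rownames(out$data) <- rec$channel_names
  list(recording = out, epochs = epochs[keep], report = rep_)
}

# mean log-probability of each epoch's channel values under a kernel density
# estimated from all epochs of that channel
epoch_log_probability <- function(epochs) {
  nc <- nrow(epochs[[1]])
  out <- matrix(NA_real_, length(epochs), nc)
  for (ch in seq_len(nc)) {
    all_x <- unlist(lapply(epochs, function(e) e[ch, ]))
    d <- stats::density(all_x, n = 512)
    f <- stats::approxfun(d$x, pmax(d$y, 1e-12), yleft = 1e-12,
                          yright = 1e-12)
    out[, ch] <- vapply(epochs, function(e) mean(log(f(e[ch, ]))), numeric(1))
  }
  out
}

#' Average-reference and downsample a cleaned recording
#'
#' Re-references to the common average, then resamples to `target_fs`:
#' a zero-phase Hamming windowed-sinc low-pass (cut-off at 90% of the target
#' Nyquist frequency) removes content that would alias, and the band-limited
#' signal is evaluated at the target sample times. The decimation factor need
#' not be an integer. Idempotent at the target rate.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz (must not exceed `rec$fs`).
#' @return The average-referenced recording at `target_fs`.
#' @export
finalize_recording <- function(rec, target_fs = 250) {
  if (target_fs > rec$fs) stop("upsampling is not supported (target_fs > fs)")
  rec <- average_reference(rec)
  if (target_fs != rec$fs) {
    fs <- rec$fs
    n <- n_samples(rec)
    cutoff <- 0.9 * target_fs / 2
    tw <- 0.2 * cutoff
    ord <- ceiling(3.3 * fs / tw)
    if (ord %% 2 == 1) ord <- ord + 1
    if (n <= ord / 2) stop("recording too short to anti-alias filter")
    b <- signal::fir1(ord, 2 * cutoff / fs, type = "low",
                      window = signal::hamming(ord + 1))
    d <- ord / 2
    t_old <- (seq_len(n) - 1) / fs
    t_new <- seq(0, t_old[n], by = 1 / target_fs)
    y <- apply(t(rec$data), 2, function(col) {
      xp <- c(col[(d + 1):2], col, col[(n - 1):(n - d)])  # mirror padding
      filt <- signal::fftfilt(b, xp)[(2 * d + 1):(2 * d + n)]
      stats::approx(t_old, filt, xout = t_new)$y
    })
    rec$data <- t(y)
    rownames(rec$data) <- rec$channel_names
    rec$fs <- target_fs
    rec <- average_reference(rec)
  }
  rec
}
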