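#' Welch power spectral density
#'
#' Averaged modified periodograms over Hamming-windowed segments (default 2 s,
#' 50% overlap), density-scaled so that the integral of the PSD over
#' frequency approximates the signal variance. Segment means are removed
#' before windowing.
#'
#' @param rec An [eeg_recording()].
#' @param window_seconds Segment length in seconds.
#' @param overlap Fractional segment overlap in \[0, 1).
#' @return A `psd` object: list with `freq` (Hz), `power` (frequencies x
#'   channels, microvolts squared per Hz), `channel_names`, `fs`.
#' @export
welch_psd <- function(rec, window_seconds = 2, overlap = 0.5) {
  fs <- rec$fs
  nwin <- round(window_seconds * fs)
  n <- n_samples(rec)
  if (n < nwin) stop("recording shorter than one Welch window")
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, n - nwin + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  U <- sum(w^2)
  nfreq <- nwin %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) * fs / nwin
  P <- matrix(0, nfreq, n_channels(rec))
  for (s in starts) {
    seg <- rec$data[, s:(s + nwin - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- stats::mvfft(t(seg * rep(w, each = nrow(seg)))[, , drop = FALSE])
    # t(seg) scaled by window: rows samples, cols channels
    P <- P + abs(ft[seq_len(nfreq), , drop = FALSE])^2
  }
  P <- P / (length(starts) * fs * U)
  scale2 <- rep(2, nfreq)
  scale2[1] <- 1
  if (nwin %% 2 == 0) scale2[nfreq] <- 1
  P <- P * scale2
  structure(list(freq = freq, power = P, channel_names = rec$channel_names,
                 fs = fs),
            class = "psd")
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the PSD over a closed frequency band, per channel.
#' Default band is theta, 4-7.5 Hz.
#'
#' @param psd A `psd` object from [welch_psd()].
#' @param band Length-2 numeric, band edges in Hz (inclusive).
#' @return Named numeric vector of band powers (microvolts squared), one per
#'   channel.
#' @export
theta_power <- function(psd, band = c(4, 7.5)) {
  if (band[1] >= band[2]) stop("band must be increasing")
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq))
    stop("band lies outside the PSD frequency range")
  sel <- psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9
  if (sum(sel) < 2) stop("band covers fewer than 2 frequency bins")
  f <- psd$freq[sel]
  out <- apply(psd$power[sel, , drop = FALSE], 2,
               function(p) pracma::trapz(f, p))
  names(out) <- psd$channel_names
  out
}

#' Aggregate channel band powers into five cortical areas
#'
#' Unweighted mean of the member-channel powers within each of the frontal,
#' central, temporal, parietal and occipital areas of the montage. Every
#' channel must be mapped to exactly one area or listed in `exclude`.
#'
#' @param powers Named numeric vector of per-channel powers.
#' @param montage Montage data.frame with `name` and `area` columns.
#' @param exclude Channel names to leave out (e.g. reference electrodes).
#' @return A data.frame with columns `area` and `power`, exactly five rows.
#' @export
group_by_area <- function(powers, montage = montage_biosemi64(),
                          exclude = character()) {
  areas <- c("frontal", "central", "temporal", "parietal", "occipital")
  nm <- setdiff(names(powers), exclude)
  unmapped <- setdiff(nm, montage$name)
  if (length(unmapped))
    stop("channel(s) not in montage: ", paste(unmapped, collapse = ", "),
         " (map them or add to 'exclude')")
  amap <- stats::setNames(montage$area, montage$name)
  data.frame(area = areas,
             power = vapply(areas, function(a)
               mean(powers[nm[amap[nm] == a]]), numeric(1)),
             row.names = NULL)
}
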