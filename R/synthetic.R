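#' Generate smooth random template topographies
#'
#' Draws `n_classes` spatially smooth scalp maps over the sensor positions by
#' sampling a Gaussian random field with a squared-exponential covariance in
#' great-circle distance, then centering (average reference) and normalizing
#' each map. Candidate maps whose absolute spatial correlation with an already
#' accepted map exceeds `max_similarity` are rejected and redrawn, so the
#' returned set is guaranteed to be mutually dissimilar.
#'
#' @param n_classes Number of template maps (2 <= n_classes < n_channels).
#' @param n_channels Number of channels. With the default 64 the shipped
#'   [montage_biosemi64()] is used; other counts get a Fibonacci cap layout.
#' @param max_similarity Maximum allowed pairwise absolute spatial correlation,
#'   in (0, 1).
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @param montage Optional data.frame with columns `name`, `x`, `y`, `z`.
#' @param length_scale Field correlation length in radians of arc.
#' @param max_retries Redraw budget per map before signalling an error.
#' @return A `template_maps` object: list with `maps` (K x N, unit-norm
#'   zero-mean rows, rownames A..), `channel_names`, `positions`.
#' @export
generate_template_maps <- function(n_classes, n_channels = 64,
                                   max_similarity = 0.7, seed = NULL,
                                   montage = NULL, length_scale = 1.2,
                                   max_retries = 200L) {
  if (n_classes < 2 || n_classes >= n_channels)
    stop("need 2 <= n_classes < n_channels")
  if (max_similarity <= 0 || max_similarity >= 1)
    stop("max_similarity must be in (0, 1)")
  if (is.null(montage) && n_channels == 64) montage <- montage_biosemi64()
  if (!is.null(montage)) {
    if (nrow(montage) != n_channels)
      stop("montage has ", nrow(montage), " channels, expected ", n_channels)
    pos <- as.matrix(montage[, c("x", "y", "z")])
    cn <- montage$name
  } else {
    pos <- fibonacci_cap(n_channels)
    cn <- paste0("ch", seq_len(n_channels))
  }
  ang <- acos(pmin(pmax(tcrossprod(pos), -1), 1))
  K <- exp(-(ang / length_scale)^2)
  ei <- eigen(K, symmetric = TRUE)           # chol can fail: K is near-singular
  L <- ei$vectors %*% diag(sqrt(pmax(ei$values, 1e-12)))
  with_seed_(seed, {
    maps <- matrix(NA_real_, n_classes, n_channels)
    for (k in seq_len(n_classes)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        v <- as.numeric(L %*% stats::rnorm(n_channels))
        v <- v - mean(v)
        v <- fix_sign(v / sqrt(sum(v^2)))
        if (k == 1 ||
            max(abs(spatial_correlation(maps[seq_len(k - 1), , drop = FALSE],
                                        v))) <= max_similarity) {
          maps[k, ] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not reach max_similarity = ", max_similarity,
             " after ", max_retries, " retries; relax the constraint")
    }
    rownames(maps) <- LETTERS[seq_len(n_classes)]
    colnames(maps) <- cn
    structure(list(maps = maps, channel_names = cn, positions = pos,
                   max_similarity = max_similarity),
              class = "template_maps")
  })
}

# quasi-uniform points on a spherical cap (used when no montage is given)
fibonacci_cap <- function(n, cap = 0.65) {
  i <- seq_len(n) - 0.5
  z <- 1 - cap * 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.template_maps <- function(x, ...) {
  cat(sprintf("<template_maps> %d classes x %d channels (max |r| <= %.2f)\n",
              nrow(x$maps), ncol(x$maps), x$max_similarity))
  invisible(x)
}

#' Microstate sequence model
#'
#' A semi-Markov model for class label sequences: a first-order chain with a
#' zero diagonal chooses the next class, and each visit dwells for a random
#' (geometric, memoryless) or fixed number of samples.
#'
#' @param n_classes Number of classes K.
#' @param transition K x K row-stochastic matrix with zero diagonal; default
#'   uniform over the other classes.
#' @param mean_dwell Expected run length in samples (>= 1), recycled to K.
#' @param dwell `"geometric"` or `"fixed"`.
#' @return A `sequence_model` object.
#' @export
sequence_model <- function(n_classes, transition = NULL, mean_dwell = 20,
                           dwell = c("geometric", "fixed")) {
  dwell <- match.arg(dwell)
  if (n_classes < 1) stop("n_classes must be >= 1")
  if (is.null(transition)) {
    transition <- matrix(1 / max(n_classes - 1, 1), n_classes, n_classes)
    diag(transition) <- 0
    if (n_classes == 1) transition <- matrix(1, 1, 1)
  }
  transition <- as.matrix(transition)
  if (any(dim(transition) != n_classes))
    stop("transition must be ", n_classes, " x ", n_classes)
  if (n_classes > 1 && any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition rows must sum to 1")
  if (n_classes > 1 && any(diag(transition) != 0))
    stop("transition diagonal must be zero (dwell is modelled separately)")
  mean_dwell <- rep_len(mean_dwell, n_classes)
  if (any(mean_dwell < 1)) stop("mean_dwell must be >= 1")
  structure(list(n_classes = n_classes, transition = transition,
                 mean_dwell = mean_dwell, dwell = dwell),
            class = "sequence_model")
}

#' Microstate label sequence
#'
#' Per-sample class labels (1..K) with sampling rate, optional per-sample
#' absolute spatial correlation and task metadata.
#'
#' @param labels Integer vector of class labels (NA = unlabeled).
#' @param fs Sampling rate in Hz.
#' @param n_classes Number of classes; default `max(labels)`.
#' @param corr Optional per-sample absolute spatial correlation in \[0, 1\].
#' @param meta Optional named list (stage, session, task_type, ...).
#' @return A `label_sequence` object.
#' @export
label_sequence <- function(labels, fs, n_classes = NULL, corr = NULL,
                           meta = list()) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("labels must be non-empty")
  n_classes <- n_classes %||% max(labels, na.rm = TRUE)
  if (any(!is.na(labels) & (labels < 1L | labels > n_classes)))
    stop("labels must lie in 1..n_classes")
  if (!is.null(corr)) {
    if (length(corr) != length(labels))
      stop("corr must have one value per sample")
    if (any(corr < -1e-9 | corr > 1 + 1e-9, na.rm = TRUE))
      stop("corr must lie in [0, 1]")
  }
  structure(list(labels = labels, fs = fs, n_classes = as.integer(n_classes),
                 corr = corr, meta = meta),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, %d classes\n",
              length(x$labels), x$fs, x$n_classes))
  invisible(x)
}

#' Sample a label sequence from a sequence model
#'
#' @param model A [sequence_model()].
#' @param n_samples Number of samples to generate (>= 1).
#' @param fs Sampling rate attached to the sequence (Hz).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [label_sequence()] with known ground-truth run structure.
#' @export
sample_label_sequence <- function(model, n_samples, fs = 250, seed = NULL) {
  if (!inherits(model, "sequence_model")) stop("model must be a sequence_model")
  if (n_samples < 1) stop("n_samples must be >= 1")
  K <- model$n_classes
  with_seed_(seed, {
    labs <- integer(0)
    cur <- sample.int(K, 1)
    while (length(labs) < n_samples) {
      d <- switch(model$dwell,
                  geometric = 1L + stats::rgeom(1, 1 / model$mean_dwell[cur]),
                  fixed = as.integer(round(model$mean_dwell[cur])))
      labs <- c(labs, rep.int(cur, d))
      cur <- if (K > 1) sample.int(K, 1, prob = model$transition[cur, ]) else cur
    }
    label_sequence(labs[seq_len(n_samples)], fs = fs, n_classes = K)
  })
}

#' Default GFP envelope
#'
#' Rectified sinusoid at an alpha-like frequency with a strictly positive
#' floor: `gfp_peak * (floor + (1 - floor) * |sin(2 pi f t)|)`. The floor
#' mirrors real data, where GFP troughs stay positive, and keeps every sample
#' classifiable; peaks occur at twice the oscillation frequency.
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate (Hz).
#' @param freq Oscillation frequency (Hz).
#' @param gfp_peak Peak global field power (microvolts).
#' @param floor Trough level as a fraction of the peak, in \[0, 1).
#' @return Numeric vector of per-sample GFP amplitudes (microvolts).
#' @export
gfp_envelope <- function(n_samples, fs, freq = 10, gfp_peak = 10,
                         floor = 0.3) {
  t <- (seq_len(n_samples) - 1) / fs
  gfp_peak * (floor + (1 - floor) * abs(sin(2 * pi * freq * t)))
}

#' Render synthetic EEG from maps and a label sequence
#'
#' Forward model: sample t equals `envelope(t) * s(t) * map[label(t), ]` (with
#' `s(t)` a per-run random polarity, exercising polarity invariance
#' downstream), plus average-referenced white sensor noise scaled so the
#' total signal-to-noise power ratio equals `snr_db`. The envelope is given in
#' GFP units (microvolts): the noiseless rendered GFP equals the envelope.
#'
#' The noise is a mixture of white sensor noise and a spatially smooth
#' background field (emulating ongoing brain activity outside the microstate
#' subspace). The background is orthogonalized against the template maps, so
#' it raises neighbouring-channel correlations to realistic levels without
#' biasing map estimation or backfitting.
#'
#' @param maps A `template_maps` object (or K x N matrix of unit-norm rows).
#' @param labels A [label_sequence()].
#' @param envelope Per-sample GFP amplitude; default [gfp_envelope()].
#' @param snr_db Signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param flip_polarity Randomly flip the sign of the rendered map per run.
#' @param background_frac Fraction of the noise power carried by the smooth
#'   background field (the rest is white), in \[0, 1\].
#' @param background_scale Correlation length of the background field
#'   (radians of arc); only used when positions are available.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An average-referenced [eeg_recording()].
#' @export
render_eeg <- function(maps, labels, envelope = NULL, snr_db = 20,
                       flip_polarity = TRUE, background_frac = 0.7,
                       background_scale = 1.2, seed = NULL) {
  M <- if (inherits(maps, "template_maps")) maps$maps else as.matrix(maps)
  cn <- if (inherits(maps, "template_maps")) maps$channel_names else
    paste0("ch", seq_len(ncol(M)))
  pos <- if (inherits(maps, "template_maps")) maps$positions else NULL
  stopifnot(inherits(labels, "label_sequence"))
  n <- length(labels$labels)
  N <- ncol(M)
  if (is.null(envelope)) envelope <- gfp_envelope(n, labels$fs)
  if (length(envelope) != n)
    stop("envelope length (", length(envelope),
         ") must equal label length (", n, ")")
  with_seed_(seed, {
    runs <- rle(labels$labels)
    sgn <- if (flip_polarity)
      rep.int(sample(c(-1, 1), length(runs$lengths), replace = TRUE),
              runs$lengths)
    else rep.int(1, n)
    # GFP (population spatial SD) of a*Gamma is a/sqrt(N) for unit-norm
    # zero-mean Gamma, so scale by sqrt(N) to render GFP = envelope
    amp <- envelope * sgn * sqrt(N)
    sig <- t(M[labels$labels, , drop = FALSE] * amp)
    if (is.finite(snr_db) && any(sig != 0)) {
      ps <- mean(sig^2)
      pn_target <- ps / 10^(snr_db / 10)
      f <- if (is.null(pos)) 0 else background_frac
      noise <- matrix(stats::rnorm(N * n), N, n)
      noise <- sweep(noise, 2, colMeans(noise))        # re-referenced noise
      noise <- noise * sqrt((1 - f) * pn_target / mean(noise^2))
      if (f > 0) {
        ang <- acos(pmin(pmax(tcrossprod(pos), -1), 1))
        ei <- eigen(exp(-(ang / background_scale)^2), symmetric = TRUE)
        L <- ei$vectors %*% diag(sqrt(pmax(ei$values, 1e-12)))
        B <- L %*% matrix(stats::rnorm(N * n), N, n)
        Q <- qr.Q(qr(t(M)))
        B <- B - Q %*% crossprod(Q, B)                 # keep maps estimable
        B <- sweep(B, 2, colMeans(B))
        noise <- noise + B * sqrt(f * pn_target / mean(B^2))
      }
      noise <- noise * sqrt(pn_target / mean(noise^2)) # exact power ratio
      sig <- sig + noise
    }
    average_reference(eeg_recording(sig, fs = labels$fs, channel_names = cn,
                                    positions = pos, reference = "average"))
  })
}

#' Training protocol description
#'
#' Stages with session counts, and the durations of the two task types within
#' each session: a short repetitive Baseline task followed by a longer varied
#' Trial task. Defaults follow the 22-session simulator protocol: stages
#' Training (7), PracticeA (8), PracticeB (7); Baseline 30 s, Trial 90 s.
#'
#' @param stages Named integer vector of sessions per stage, in order.
#' @param baseline_duration,trial_duration Task durations in seconds.
#' @param sampling_rate Sampling rate of the simulated recordings (Hz).
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(stages = c(Training = 7, PracticeA = 8, PracticeB = 7),
                          baseline_duration = 30, trial_duration = 90,
                          sampling_rate = 250) {
  if (baseline_duration <= 0 || trial_duration <= 0 || sampling_rate <= 0)
    stop("durations and sampling rate must be positive")
  if (is.null(names(stages)) || any(stages < 1))
    stop("stages must be a named vector of positive session counts")
  structure(list(stages = stages, baseline_duration = baseline_duration,
                 trial_duration = trial_duration,
                 sampling_rate = sampling_rate),
            class = "protocol_spec")
}

#' Simulate one participant's full training protocol
#'
#' For every session of every stage, samples a Baseline and a Trial label
#' sequence from the corresponding sequence model and renders both to EEG.
#'
#' @param spec A [protocol_spec()].
#' @param maps A `template_maps` object shared by all tasks.
#' @param baseline_model,trial_model [sequence_model()]s for the two task
#'   types; defaults are uniform models with mean dwells of 22 and 18 samples.
#' @param snr_db Rendering signal-to-noise ratio in dB.
#' @param seed Integer seed for the whole protocol.
#' @return List of task items, each a list with `stage`, `session`,
#'   `task_type`, `recording`, `labels`.
#' @export
simulate_protocol <- function(spec = protocol_spec(), maps,
                              baseline_model = NULL, trial_model = NULL,
                              snr_db = 20, seed = NULL) {
  K <- nrow(if (inherits(maps, "template_maps")) maps$maps else maps)
  baseline_model <- baseline_model %||% sequence_model(K, mean_dwell = 22)
  trial_model <- trial_model %||% sequence_model(K, mean_dwell = 18)
  fs <- spec$sampling_rate
  with_seed_(seed, {
    out <- list()
    for (st in names(spec$stages)) {
      for (ses in seq_len(spec$stages[[st]])) {
        for (tt in c("Baseline", "Trial")) {
          dur <- if (tt == "Baseline") spec$baseline_duration else
            spec$trial_duration
          model <- if (tt == "Baseline") baseline_model else trial_model
          labs <- sample_label_sequence(model, round(dur * fs), fs = fs)
          labs$meta <- list(stage = st, session = ses, task_type = tt)
          rec <- render_eeg(maps, labs, snr_db = snr_db)
          out[[length(out) + 1]] <- list(stage = st, session = ses,
                                         task_type = tt, recording = rec,
                                         labels = labs)
        }
      }
    }
    out
  })
}

#' Sample a +/-1 sequence with a prescribed Hurst exponent
#'
#' Generates a stationary Gaussian process whose autocorrelation is chosen so
#' that, after sign-clipping, the binary sequence has exactly the fractional
#' Gaussian noise autocorrelation of the target Hurst exponent (the arcsine
#' law for clipped Gaussians: a Gaussian correlation of `sin(pi rho / 2)`
#' yields a clipped correlation of `rho`). Simulation is by circulant
#' embedding.
#'
#' @param hurst_target Target Hurst exponent in (0, 1).
#' @param n_samples Sequence length (>= 500 for a meaningful DFA).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Numeric vector of -1/+1 values.
#' @export
sample_correlated_pm1 <- function(hurst_target, n_samples, seed = NULL) {
  if (hurst_target <= 0 || hurst_target >= 1)
    stop("hurst_target must be in (0, 1)")
  if (n_samples < 500) stop("n_samples must be >= 500 for DFA use")
  H <- hurst_target
  k <- 0:n_samples
  rho <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  g <- sin(pi * rho / 2)
  with_seed_(seed, {
    x <- circulant_gaussian(n_samples, g)
    s <- sign(x)
    s[s == 0] <- 1
    s
  })
}

# stationary Gaussian sample with autocovariance g[1..n+1] (lags 0..n),
# circulant embedding; tiny negative eigenvalues are clipped
circulant_gaussian <- function(n, g) {
  c_ <- c(g, g[n:2])
  m <- length(c_)
  lam <- Re(stats::fft(c_))
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(lam) * z))[1:n] / sqrt(m)
}
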