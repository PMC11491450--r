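# Spherical-spline channel interpolation (Perrin-style).
# g(x) = (1/4pi) sum_{n=1..nterms} (2n+1) / (n(n+1))^m  P_n(x)
# with stiffness m = 4, 7-term Legendre truncation and ridge regularization.

legendre_table <- function(x, nmax) {
  x <- pmin(pmax(x, -1), 1)
  P <- matrix(0, nmax, length(x))
  p0 <- rep(1, length(x)); p1 <- x
  P[1, ] <- x
  if (nmax >= 2) {
    for (nn in 2:nmax) {
      p2 <- ((2 * nn - 1) * x * p1 - (nn - 1) * p0) / nn
      P[nn, ] <- p2
      p0 <- p1; p1 <- p2
    }
  }
  P
}

spline_g <- function(cosang, m = 4, nterms = 7) {
  P <- legendre_table(as.numeric(cosang), nterms)
  nn <- seq_len(nterms)
  w <- (2 * nn + 1) / (nn * (nn + 1))^m
  out <- as.numeric(w %*% P) / (4 * pi)
  if (is.matrix(cosang)) matrix(out, nrow(cosang)) else out
}

# interpolate columns of a channels x samples matrix at bad channel indices
spline_interp_matrix <- function(data, positions, bad, m = 4, lambda = 1e-5,
                                 nterms = 7) {
  good <- setdiff(seq_len(nrow(data)), bad)
  if (length(good) < 4) stop("spherical-spline interpolation needs >= 4 good channels")
  G <- spline_g(tcrossprod(positions[good, , drop = FALSE]), m, nterms)
  A <- rbind(cbind(G + lambda * diag(length(good)), 1),
             c(rep(1, length(good)), 0))
  rhs <- rbind(data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  Gb <- spline_g(positions[bad, , drop = FALSE] %*%
                   t(positions[good, , drop = FALSE]), m, nterms)
  data[bad, ] <- cbind(Gb, 1) %*% sol
  data
}

#' Interpolate bad channels with spherical splines
#'
#' Replaces the listed channels by Perrin-style spherical-spline estimates
#' from the remaining channels (stiffness order 4, 7-term Legendre expansion,
#' ridge regularization 1e-5). Good channels are returned bit-identical.
#'
#' @param rec An [eeg_recording()] with sensor positions.
#' @param bad Channel names or indices to interpolate.
#' @param m Spline stiffness order.
#' @param lambda Ridge regularization added to the spline system.
#' @param nterms Number of Legendre terms.
#' @return The recording with bad channels replaced.
#' @export
interpolate_spherical <- function(rec, bad, m = 4, lambda = 1e-5, nterms = 7) {
  if (is.null(rec$positions))
    stop("interpolation needs sensor positions")
  if (is.character(bad)) bad <- match(bad, rec$channel_names)
  if (any(is.na(bad))) stop("unknown channel in 'bad'")
  if (length(bad) == 0) return(rec)
  rec$data <- spline_interp_matrix(rec$data, rec$positions, bad, m, lambda,
                                   nterms)
  rec
}
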