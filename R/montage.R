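#' 64-channel extended 10-20 montage
#'
#' Channel names, approximate unit-sphere sensor positions, and the mapping of
#' each channel into one of five cortical areas (frontal, central, temporal,
#' parietal, occipital). Positions are computed from the schematic row /
#' lateral-index layout of the extended 10-20 system projected onto the unit
#' sphere; they are smooth, unique and unit-norm, which is what neighbour
#' detection, spherical-spline interpolation and synthetic topography
#' generation require. They are not digitized head coordinates.
#'
#' @return A data.frame with columns `name`, `x`, `y`, `z` (unit-norm, x right,
#'   y front, z up) and `area`.
#' @export
montage_biosemi64 <- function() {
  nm <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
          "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
          "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
          "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
          "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
          "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
          "P10", "PO8", "PO4", "O2")
  pos <- t(vapply(nm, channel_position, numeric(3)))
  data.frame(name = nm, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             area = vapply(nm, channel_area, character(1)),
             stringsAsFactors = FALSE)
}

# front-back row value (units of 10% arcs from the vertex, front positive)
.row_values <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, T = 0,
                 TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -5)

parse_channel <- function(name) {
  row <- sub("^([A-Za-z]+?)(z|[0-9]+)$", "\\1", name)
  suf <- sub("^([A-Za-z]+?)(z|[0-9]+)$", "\\2", name)
  if (!row %in% names(.row_values))
    stop("unrecognized channel name: ", name)
  if (suf == "z") {
    lat <- 0
  } else {
    k <- as.integer(suf)
    lat <- ceiling(k / 2) * ifelse(k %% 2 == 1, -1, 1)  # odd = left
  }
  c(row = unname(.row_values[row]), lat = lat)
}

channel_position <- function(name) {
  p <- parse_channel(name)
  r2 <- sqrt(p["row"]^2 + p["lat"]^2)
  theta <- (18 * pi / 180) * r2            # inclination from the vertex
  if (r2 == 0) return(c(0, 0, 1))
  u <- c(p["lat"], p["row"]) / r2          # schematic direction (right, front)
  unname(c(sin(theta) * u[1], sin(theta) * u[2], cos(theta)))
}

channel_area <- function(name) {
  row <- sub("^([A-Za-z]+?)(z|[0-9]+)$", "\\1", name)
  switch(row,
         Fp = , AF = , F = "frontal",
         FC = , C = "central",
         FT = , T = , TP = "temporal",
         CP = , P = "parietal",
         PO = , O = , I = "occipital",
         stop("unrecognized channel name: ", name))
}

#' Find nearest neighbouring channels
#'
#' Neighbourhood by great-circle distance on the unit sphere.
#'
#' @param positions n x 3 matrix of unit-norm sensor positions.
#' @param n_neighbors Number of neighbours per channel.
#' @return Integer matrix, one row per channel, of neighbour indices.
#' @keywords internal
nearest_neighbors <- function(positions, n_neighbors = 4) {
  cosang <- tcrossprod(positions)
  diag(cosang) <- -Inf
  t(apply(cosang, 1, function(r)
    order(r, decreasing = TRUE)[seq_len(n_neighbors)]))
}
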