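#' Spatial correlation between topographies
#'
#' Pearson correlation across channels between two scalp maps, the standard
#' similarity measure for microstate topographies. For average-referenced,
#' zero-mean maps this equals the cosine similarity.
#'
#' @param a,b Numeric vectors (one map each) or matrices with maps in rows.
#' @param absolute If `TRUE`, return absolute values (polarity ignored).
#' @return A scalar (two vectors) or a matrix with entry `[i, j]` the
#'   correlation between row `i` of `a` and row `j` of `b`.
#' @export
spatial_correlation <- function(a, b, absolute = FALSE) {
  if (is.vector(a) && is.vector(b)) {
    r <- stats::cor(a, b)
    return(if (absolute) abs(r) else r)
  }
  a <- rbind(a); b <- rbind(b)
  r <- stats::cor(t(a), t(b))
  if (absolute) abs(r) else r
}

# evaluate code under a temporary RNG seed, restoring global RNG state;
# seed = NULL means "use the current RNG stream" (for nested generators)
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# row-normalize to unit Euclidean norm
unit_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

# deterministic sign convention: largest-magnitude component positive
fix_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) s <- 1
  v * s
}

# all permutations of 1..k in lexicographic order (k! rows)
perms_lex <- function(k) {
  p <- pracma::perms(seq_len(k))
  p[do.call(order, as.data.frame(p)), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
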