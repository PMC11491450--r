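#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Balanced fully-within-subject ANOVA for one to three within factors.
#' Sums of squares come from the orthogonal averaging/centering decomposition
#' of the subject-by-cells data array; each within effect is tested against
#' its interaction with subjects. The Greenhouse-Geisser epsilon of every
#' multi-df effect is computed from the covariance of the subjects' scores on
#' the effect's orthonormal contrasts, and both the uncorrected and the
#' epsilon-corrected p values are reported, together with partial eta
#' squared.
#'
#' @param data Long-format data.frame with one observation per subject and
#'   cell of the complete within-subject crossing.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of within-factor column names (1-3).
#' @return An `anova_table` data.frame: `effect`, `df1`, `df2`, `ss`,
#'   `ss_error`, `F`, `p`, `gg_epsilon`, `p_gg`, `peta2`.
#' @export
rm_anova <- function(data, dv = "value", subject = "participant",
                     within) {
  if (length(within) < 1 || length(within) > 3)
    stop("supply 1 to 3 within-subject factors")
  for (cl in c(dv, subject, within))
    if (!cl %in% names(data)) stop("column not found: ", cl)
  subj <- factor(data[[subject]])
  if (nlevels(subj) < 2) stop("need >= 2 participants")
  facs <- lapply(within, function(f) factor(data[[f]]))
  lv <- vapply(facs, nlevels, 0L)
  idx <- do.call(cbind, c(list(as.integer(subj)),
                          lapply(facs, as.integer)))
  dims <- c(nlevels(subj), lv)
  if (nrow(data) != prod(dims) ||
      anyDuplicated(idx))
    stop("design is not a complete crossing with one observation per cell")
  Y <- array(NA_real_, dims)
  Y[idx] <- data[[dv]]
  n <- dims[1]
  wf <- seq_along(within) + 1L          # within dims in Y
  S <- stats::cov(matrix(Y, n))         # subject x cells covariance
  effects <- unlist(lapply(seq_along(wf), function(m)
    lapply(utils::combn(length(wf), m, simplify = FALSE),
           function(ix) wf[ix])),
    recursive = FALSE)
  rows <- lapply(effects, function(E) {
    ss <- sum(effect_component(Y, E)^2)
    sse <- sum(effect_component(Y, c(1L, E))^2)
    df1 <- prod(dims[E] - 1)
    df2 <- (n - 1) * df1
    Fv <- (ss / df1) / (sse / df2)
    Cl <- lapply(wf, function(d)
      if (d %in% E) orthonormal_contrasts(dims[d])
      else matrix(1 / sqrt(dims[d]), dims[d], 1))
    Cf <- Reduce(function(a, b) kronecker(b, a), Cl)
    Sg <- crossprod(Cf, S %*% Cf)
    eps <- if (df1 > 1)
      min(1, max(1 / df1, sum(diag(Sg))^2 / (df1 * sum(Sg^2))))
    else 1
    data.frame(effect = paste(within[E - 1L], collapse = ":"),
               df1 = df1, df2 = df2, ss = ss, ss_error = sse, F = Fv,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               gg_epsilon = eps,
               p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               peta2 = ss / (ss + sse))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

# mean over dimension d of array A, broadcast back to A's shape
dim_mean <- function(A, d) {
  nd <- length(dim(A))
  m <- apply(A, (1:nd)[-d], mean)
  B <- array(m, dim = dim(A)[c((1:nd)[-d], d)])
  aperm(B, order(c((1:nd)[-d], d)))
}

# orthogonal component of the balanced decomposition: centre the dimensions
# in `keep`, average out all others
effect_component <- function(A, keep) {
  for (d in seq_along(dim(A)))
    A <- if (d %in% keep) A - dim_mean(A, d) else dim_mean(A, d)
  A
}

orthonormal_contrasts <- function(p) {
  C <- stats::contr.helmert(p)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Post-hoc paired t tests with Bonferroni correction
#'
#' Two-sided paired t tests between levels of `compare`, run separately at
#' each level of `per_level_of` (after averaging the dependent variable over
#' any remaining factors within subject), with p values multiplied by the
#' family size and capped at 1. The family defaults to all comparisons the
#' call generates.
#'
#' @inheritParams rm_anova
#' @param compare Factor whose levels are compared pairwise.
#' @param per_level_of Optional stratifying factor.
#' @param family_size Bonferroni family size; default the number of
#'   comparisons generated by this call.
#' @return A data.frame with one row per comparison: stratum, the two levels,
#'   `t`, `df`, `p`, `p_bonf`, `marker`.
#' @export
posthoc_paired_bonferroni <- function(data, dv = "value",
                                      subject = "participant", compare,
                                      per_level_of = NULL,
                                      family_size = NULL) {
  if (length(unique(data[[subject]])) < 3)
    stop("need >= 3 participants for paired t tests")
  strata <- if (is.null(per_level_of)) list(NULL)
            else as.list(unique(as.character(data[[per_level_of]])))
  lev <- unique(as.character(data[[compare]]))
  prs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- list()
  for (st in strata) {
    d <- if (is.null(st)) data else data[data[[per_level_of]] == st, ]
    agg <- stats::aggregate(d[[dv]],
                            by = list(subject = d[[subject]],
                                      level = d[[compare]]), FUN = mean)
    for (pr in prs) {
      a <- agg$x[agg$level == pr[1]][order(agg$subject[agg$level == pr[1]])]
      b <- agg$x[agg$level == pr[2]][order(agg$subject[agg$level == pr[2]])]
      dd <- a - b
      if (all(dd == 0)) {           # degenerate: no difference at all
        tv <- 0; dfv <- length(dd) - 1; pv <- 1
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        tv <- unname(tt$statistic); dfv <- unname(tt$parameter)
        pv <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum = if (is.null(st)) NA_character_ else st,
        level_a = pr[1], level_b = pr[2], t = tv, df = dfv, p = pv)
    }
  }
  out <- do.call(rbind, rows)
  m <- family_size %||% nrow(out)
  out$p_bonf <- pmin(1, out$p * m)
  out$marker <- significance_annotation(out$p_bonf)
  out
}

#' Significance markers
#'
#' `***` for p <= 0.005, `**` for p <= 0.010, `*` for p <= 0.050, empty
#' otherwise.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of markers.
#' @export
significance_annotation <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  ifelse(p <= 0.005, "***",
         ifelse(p <= 0.010, "**",
                ifelse(p <= 0.050, "*", "")))
}
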