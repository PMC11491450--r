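#' Align microstate map sets by full permutation
#'
#' Aggregates several K-map sets (per subject or per task) into one global
#' set. Iteratively, each member set is matched to the current mean maps by
#' exhaustive search over all K! label permutations (polarity resolved per
#' class by the sign of the correlation), then the mean maps are recomputed as
#' the sign-aligned, re-normalized average. The objective - the mean absolute
#' spatial correlation between members and the mean maps - is non-decreasing
#' across iterations; iteration stops when the assignments stabilize.
#'
#' @param members List of K x N matrices, `template_maps`, or
#'   `microstate_solution` objects (>= 2 members, common K and channel order).
#' @param max_iter Maximum alignment sweeps.
#' @return List with `global_maps` (K x N unit-norm, zero-mean rows),
#'   `alignment` (per member: `perm`, `signs`), `objective`, `n_iter`.
#' @export
align_full_permutation <- function(members, max_iter = 50) {
  mats <- lapply(members, function(m) {
    if (inherits(m, "template_maps")) m$maps
    else if (inherits(m, "microstate_solution")) m$maps
    else as.matrix(m)
  })
  if (length(mats) < 2) stop("need >= 2 member map sets")
  K <- nrow(mats[[1]])
  if (K > 8) stop("full-permutation search is limited to K <= 8")
  if (any(vapply(mats, nrow, 0L) != K) ||
      any(vapply(mats, ncol, 0L) != ncol(mats[[1]])))
    stop("all members must share K and channel count")
  P <- perms_lex(K)
  mean_maps <- unit_rows(mats[[1]])
  perm_prev <- NULL
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    al <- lapply(mats, match_one, mean_maps = mean_maps, P = P)
    obj <- mean(vapply(al, `[[`, 0, "score"))
    if (obj < obj_prev - 1e-12) {
      warning("alignment objective decreased; returning previous state")
      break
    }
    obj_prev <- obj
    perms_now <- lapply(al, `[[`, "perm")
    acc <- matrix(0, K, ncol(mean_maps))
    for (i in seq_along(mats))
      acc <- acc + mats[[i]][al[[i]]$perm, , drop = FALSE] * al[[i]]$signs
    mean_maps <- unit_rows(sweep(acc, 1, rowMeans(acc)))
    if (!is.null(perm_prev) && identical(perms_now, perm_prev)) break
    perm_prev <- perms_now
  }
  if (it == max_iter)
    warning("alignment did not stabilize in ", max_iter, " sweeps")
  mean_maps <- t(apply(mean_maps, 1, fix_sign))
  colnames(mean_maps) <- colnames(mats[[1]])
  list(global_maps = mean_maps,
       alignment = lapply(al, function(a) a[c("perm", "signs")]),
       objective = obj_prev, n_iter = it)
}

# best permutation (and per-class signs) of `member` against `mean_maps`
match_one <- function(member, mean_maps, P) {
  K <- nrow(mean_maps)
  C <- spatial_correlation(mean_maps, member)      # K x K, mean vs member
  A <- abs(C)
  sc <- rowSums(vapply(seq_len(K), function(k) A[k, P[, k]],
                       numeric(nrow(P))))
  best <- which.max(sc)                            # first max = lexicographic
  perm <- P[best, ]
  signs <- sign(C[cbind(seq_len(K), perm)])
  signs[signs == 0] <- 1
  list(perm = perm, signs = signs, score = sc[best] / K)
}

#' Label global maps against canonical templates
#'
#' Finds the one-to-one assignment between candidate maps and the template
#' maps that maximizes the total absolute spatial correlation (exhaustive
#' search over the K! assignments), and returns the maps reordered to the
#' template order with labels A..G attached. Ties are broken toward the
#' lexicographically first assignment (lowest template index) with a warning.
#'
#' @param global_maps K x N matrix of candidate maps.
#' @param templates A `template_maps` object (same channel set).
#' @return A `template_maps`-like object with rows ordered and labelled A..G,
#'   plus attributes `assignment` (template index -> input row) and `score`.
#' @export
label_canonical <- function(global_maps, templates) {
  M <- if (inherits(global_maps, "microstate_solution")) global_maps$maps
       else as.matrix(global_maps)
  Tm <- templates$maps
  if (ncol(M) != ncol(Tm))
    stop("channel sets of maps and templates differ")
  K <- nrow(Tm)
  if (nrow(M) != K) stop("need as many candidate maps as templates")
  P <- perms_lex(K)
  A <- abs(spatial_correlation(Tm, M))             # template x candidate
  sc <- rowSums(vapply(seq_len(K), function(k) A[k, P[, k]],
                       numeric(nrow(P))))
  mx <- max(sc)
  if (sum(abs(sc - mx) < 1e-12) > 1)
    warning("ties in canonical labelling; using lowest template index first")
  perm <- P[which.max(sc), ]
  out <- M[perm, , drop = FALSE]
  rownames(out) <- rownames(Tm)
  structure(list(maps = out, channel_names = templates$channel_names,
                 positions = templates$positions,
                 max_similarity = templates$max_similarity),
            class = "template_maps",
            assignment = perm, score = mx)
}

#' Canonical template topographies (synthetic stand-ins)
#'
#' Seven idealized topographies labelled A-G, generated by the package's own
#' smooth-field generator under a fixed seed. They provide a deterministic,
#' shareable labelling reference; they are synthetic stand-ins, not published
#' microstate templates, and users with montage-matched templates of their
#' own should pass those instead.
#'
#' @param montage Montage data.frame; default [montage_biosemi64()].
#' @return A `template_maps` object with 7 maps labelled A-G.
#' @export
canonical_templates <- function(montage = montage_biosemi64()) {
  generate_template_maps(7, nrow(montage), max_similarity = 0.7,
                         seed = 7919L, montage = montage)
}
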