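#' Coincidence index of two equally sized selection sets
#'
#' The fraction of shared members between two top-`k` selection sets:
#' `|intersection| / k`. Symmetric, bounded in `[0, 1]`, and 1 exactly when
#' the sets are equal.
#'
#' @param p_set,q_set Character vectors of selected identifiers, each of
#'   length `k` (no duplicates).
#' @param k Selection intensity.
#' @return A number in `[0, 1]`.
#' @export
coincidence_index <- function(p_set, q_set, k) {
  p_set <- unique(as.character(p_set)); q_set <- unique(as.character(q_set))
  if (length(p_set) != k || length(q_set) != k)
    stop_recsel("coincidence_index: both sets must have exactly k = %d members", k)
  length(intersect(p_set, q_set)) / k
}

#' Normalized coincidence of two selection sets
#'
#' `|intersection| / min(|p|, |q|)`: the coincidence form used when the
#' compared sets differ in size. A subset scores 1; for equal sizes it
#' equals [coincidence_index()].
#'
#' @param p_set,q_set Non-empty character vectors of selected identifiers.
#' @return A number in `[0, 1]`.
#' @export
normalized_coincidence <- function(p_set, q_set) {
  p_set <- unique(as.character(p_set)); q_set <- unique(as.character(q_set))
  if (!length(p_set) || !length(q_set))
    stop_recsel("normalized_coincidence: both sets must be non-empty")
  length(intersect(p_set, q_set)) / min(length(p_set), length(q_set))
}

#' Jaccard similarity of two selection sets
#'
#' `|intersection| / |union|`. The most conservative of the three overlap
#' measures: `jaccard <= coincidence_index <= normalized_coincidence` at
#' matched set sizes.
#'
#' @param p_set,q_set Character vectors of selected identifiers with a
#'   non-empty union.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(p_set, q_set) {
  p_set <- unique(as.character(p_set)); q_set <- unique(as.character(q_set))
  u <- length(union(p_set, q_set))
  if (!u) stop_recsel("jaccard: union of the sets is empty")
  length(intersect(p_set, q_set)) / u
}

#' Collection of strategy rankings for coincidence analysis
#'
#' @param rankings Named list of ordered identifier vectors (best first),
#'   one per strategy; each must be a permutation of the shared candidate
#'   universe (or a prefix-consistent ranking of it covering
#'   `max(k_grid)`).
#' @param universe Candidate universe; default: the union of all rankings.
#' @param k_grid Selection intensities to evaluate (ascending).
#' @return An object of class `selection_collection`.
#' @export
selection_collection <- function(rankings, universe = NULL,
                                 k_grid = c(10L, 20L, 30L, 40L)) {
  if (is.null(names(rankings)) || any(!nzchar(names(rankings))))
    stop_recsel("rankings must be a named list")
  rankings <- lapply(rankings, function(r) {
    if (inherits(r, "selection_result")) r$ranking else as.character(r)
  })
  if (any(vapply(rankings, anyDuplicated, 0L) > 0))
    stop_recsel("rankings must not contain duplicate identifiers")
  if (is.null(universe)) universe <- sort(unique(unlist(rankings)))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > length(universe)))
    stop_recsel("k_grid values must lie in 1..|universe| (= %d)", length(universe))
  short <- vapply(rankings, length, 0L) < max(k_grid)
  if (any(short))
    stop_recsel("ranking(s) shorter than max(k_grid): %s",
                paste(names(rankings)[short], collapse = ", "))
  structure(list(universe = universe, rankings = rankings, k_grid = k_grid),
            class = "selection_collection")
}

top_sets <- function(collection, k)
  lapply(collection$rankings, function(r) r[seq_len(k)])

measure_fun <- function(measure, k) {
  switch(measure,
         ci = function(p, q) coincidence_index(p, q, k),
         normalized = normalized_coincidence,
         jaccard = jaccard)
}

#' Pairwise agreement matrix among strategies at one intensity
#'
#' @param collection A [selection_collection()].
#' @param k Selection intensity.
#' @param measure `"ci"` (plain coincidence), `"normalized"`, or
#'   `"jaccard"`.
#' @return A symmetric strategy-by-strategy matrix with unit diagonal.
#' @export
pairwise_matrix <- function(collection, k,
                            measure = c("jaccard", "ci", "normalized")) {
  measure <- match.arg(measure)
  sets <- top_sets(collection, k)
  M <- length(sets)
  f <- measure_fun(measure, k)
  out <- matrix(1, M, M, dimnames = list(names(sets), names(sets)))
  if (M > 1) for (i in 1:(M - 1)) for (j in (i + 1):M)
    out[i, j] <- out[j, i] <- f(sets[[i]], sets[[j]])
  out
}

#' Mean pairwise agreement among strategies
#'
#' The unweighted mean of the chosen overlap measure over all unordered
#' strategy pairs: `2 / (M (M - 1)) * sum_{p<q} CI_{p,q}(k)`.
#'
#' @inheritParams pairwise_matrix
#' @return A number in `[0, 1]`.
#' @export
mean_pairwise <- function(collection, k,
                          measure = c("ci", "jaccard", "normalized")) {
  measure <- match.arg(measure)
  if (length(collection$rankings) < 2L)
    stop_recsel("mean_pairwise needs at least 2 strategies")
  P <- pairwise_matrix(collection, k, measure)
  mean(P[upper.tri(P)])
}

#' Agreement curve over selection intensity
#'
#' Evaluates the mean pairwise agreement at each intensity of the
#' collection's `k_grid` and also retains the full pairwise matrix per `k`
#' (heatmap-ready) in `attr(, "matrices")`.
#'
#' @inheritParams pairwise_matrix
#' @return A data frame `(k, mean_pairwise)` with the per-`k` matrices as
#'   an attribute.
#' @export
coincidence_curve <- function(collection,
                              measure = c("ci", "jaccard", "normalized")) {
  measure <- match.arg(measure)
  mats <- lapply(collection$k_grid, function(k)
    pairwise_matrix(collection, k, measure))
  names(mats) <- paste0("k", collection$k_grid)
  out <- data.frame(k = collection$k_grid,
                    mean_pairwise = vapply(mats, function(P) mean(P[upper.tri(P)]),
                                           0))
  rownames(out) <- NULL
  attr(out, "matrices") <- mats
  attr(out, "measure") <- measure
  out
}

#' Membership matrix of selected progenies
#'
#' A 0/1 progeny-by-strategy matrix indicating which progenies each
#' strategy selects at intensity `k` — the data behind a selection-overlap
#' heatmap. Rows are ordered so that progenies selected by most strategies
#' come first.
#'
#' @inheritParams pairwise_matrix
#' @return An integer 0/1 matrix (progeny x strategy).
#' @export
membership_matrix <- function(collection, k) {
  sets <- top_sets(collection, k)
  ids <- collection$universe
  M <- vapply(sets, function(s) as.integer(ids %in% s), integer(length(ids)))
  rownames(M) <- ids
  M <- M[order(-rowSums(M), rownames(M)), , drop = FALSE]
  M
}
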