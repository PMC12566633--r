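new_selection_result <- function(strategy, scores, ranking, higher_better,
                                 selected = NULL, k = NA_integer_, extra = list()) {
  structure(c(list(strategy = strategy, scores = scores, ranking = ranking,
                   selected = selected, k = k, higher_better = higher_better),
              extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection strategy %s: %d candidates", x$strategy, length(x$scores)))
  if (!is.na(x$k)) cat(sprintf(", top %d selected", x$k))
  cat("\n  best 5:", paste(utils::head(x$ranking, 5), collapse = ", "), "\n")
  invisible(x)
}

# Standardized, direction-adjusted family-mean matrix. When `scale_tab`
# (from a genetic_params fit) is given its constants are reused so indexes
# and P/G live on the identical scale; otherwise constants are computed over
# the candidates in `fm`.
standardized_means <- function(fm, traits, directions = NULL, scale_tab = NULL,
                               require_sd = traits) {
  M <- means_matrix(fm)
  missing <- setdiff(traits, colnames(M))
  if (length(missing))
    stop_recsel("trait(s) absent from family means: %s", paste(missing, collapse = ", "))
  M <- M[, traits, drop = FALSE]
  if (!is.null(scale_tab)) {
    idx <- match(traits, scale_tab$trait)
    if (anyNA(idx)) stop_recsel("scale constants missing for some traits")
    center <- scale_tab$center[idx]; sds <- scale_tab$sd[idx]; sgn <- scale_tab$sign[idx]
  } else {
    if (is.null(directions))
      directions <- stats::setNames(rep("maximize", length(traits)), traits)
    center <- colMeans(M, na.rm = TRUE)
    sds <- apply(M, 2, stats::sd, na.rm = TRUE)
    sgn <- ifelse(directions[traits] == "minimize", -1, 1)
  }
  zero_sd <- traits[sds <= 0 & traits %in% require_sd]
  if (length(zero_sd))
    stop_recsel("zero SD among family means for standardized trait(s): %s",
                paste(zero_sd, collapse = ", "))
  sds[sds <= 0] <- 1
  Z <- sweep(sweep(M, 2, center), 2, sds, "/")
  sweep(Z, 2, sgn, "*")
}

weights_vector <- function(weights, traits) {
  if (is.null(names(weights)))
    stop_recsel("economic weights must be a named numeric vector")
  unknown <- setdiff(names(weights)[weights != 0], traits)
  if (length(unknown))
    stop_recsel("weights refer to trait(s) not available: %s",
                paste(unknown, collapse = ", "))
  a <- stats::setNames(rep(0, length(traits)), traits)
  a[intersect(names(weights), traits)] <- weights[intersect(names(weights), traits)]
  if (all(a == 0)) stop_recsel("at least one weight must be nonzero")
  a
}

#' Base selection index
#'
#' Scores each progeny by the economic-weighted sum of its standardized,
#' direction-adjusted trait means: `score_j = sum_t a_t z_jt`, where `z_jt`
#' is the family mean of trait `t` centred and scaled over candidate
#' progenies and sign-flipped for minimize-traits. With weights grain
#' yield = 2 and inbreeding depression = 1 (all other traits 0) this is the
#' classical base index of a yield/depression selection programme.
#'
#' @param means A `family_means` table of candidate progenies
#'   ([family_means()]).
#' @param weights Named numeric vector of economic weights; traits with
#'   weight 0 are carried but exert no selection pressure.
#' @param directions Named vector (`"maximize"`/`"minimize"`) per trait;
#'   default all maximize.
#' @param traits Traits spanning the index (default: all traits in
#'   `means`).
#' @return A `selection_result` with `scores` (higher is better), the full
#'   `ranking` (ties broken by progeny identifier), and `strategy = "BIA"`.
#' @export
base_index <- function(means, weights, directions = NULL, traits = NULL) {
  if (is.null(traits)) traits <- unique(means$trait)
  a <- weights_vector(weights, traits)
  Z <- standardized_means(means, traits, directions,
                          require_sd = names(a)[a != 0])
  Z[is.na(Z)] <- 0
  scores <- drop(Z %*% a)
  names(scores) <- rownames(Z)
  new_selection_result("BIA", scores,
                       order_scores(scores, decreasing = TRUE),
                       higher_better = TRUE, extra = list(weights = a))
}

#' Smith–Hazel selection index
#'
#' Computes the optimal linear index `b' z` with weights obtained from the
#' phenotypic and genotypic covariance matrices of family means: `b` solves
#' `P b = G a` (a linear solve, never an explicit inversion), where `a`
#' holds the economic weights. The index is evaluated on standardized,
#' direction-adjusted family means using the same scale constants on which
#' `P` and `G` were estimated, which makes the base and Smith–Hazel indexes
#' commensurable.
#'
#' @param means A `family_means` table of candidate progenies.
#' @param params A `genetic_params` object from [estimate_PG()].
#' @param weights Named numeric vector of economic weights.
#' @return A `selection_result` with `strategy = "SHI"`; the solved index
#'   weights are in `$b`.
#' @export
smith_hazel <- function(means, params, weights) {
  stopifnot(inherits(params, "genetic_params"))
  traits <- params$traits
  a <- weights_vector(weights, traits)
  if (max(abs(params$G)) == 0) {
    warn_recsel("G is the zero matrix (no heritable variation): all index scores are 0")
    b <- stats::setNames(rep(0, length(traits)), traits)
  } else {
    b <- drop(solve(params$P, params$G %*% a))
    names(b) <- traits
  }
  Z <- standardized_means(means, traits, scale_tab = params$scale,
                          require_sd = character())
  Z[is.na(Z)] <- 0
  scores <- drop(Z %*% b)
  names(scores) <- rownames(Z)
  new_selection_result("SHI", scores,
                       order_scores(scores, decreasing = TRUE),
                       higher_better = TRUE,
                       extra = list(b = b, weights = a))
}

#' Mulamba–Mock rank-summation index
#'
#' Ranks progenies trait by trait (rank 1 = best: largest value for
#' maximize-traits, smallest for minimize-traits such as inbreeding
#' depression; ties receive average ranks) and scores each progeny by the
#' weighted sum of its ranks. Smaller totals are better. The index is
#' invariant to any strictly monotone per-trait transformation of the
#' means.
#'
#' @inheritParams base_index
#' @return A `selection_result` with `strategy = "MMI"`; `scores` are rank
#'   sums (lower is better) and `ranking` ascends by score with ties broken
#'   by progeny identifier.
#' @export
rank_sum <- function(means, weights, directions = NULL, traits = NULL) {
  if (is.null(traits)) traits <- unique(means$trait)
  a <- weights_vector(weights, traits)
  M <- means_matrix(means)[, traits, drop = FALSE]
  if (nrow(M) < 2L) stop_recsel("rank_sum needs at least 2 progenies")
  if (is.null(directions))
    directions <- stats::setNames(rep("maximize", length(traits)), traits)
  sgn <- ifelse(directions[traits] == "minimize", -1, 1)
  Rk <- vapply(seq_along(traits), function(j) {
    v <- sgn[j] * M[, j]
    rank(-v, ties.method = "average", na.last = "keep")
  }, numeric(nrow(M)))
  Rk[is.na(Rk)] <- (nrow(M) + 1) / 2 # missing trait mean: neutral mid rank
  scores <- drop(Rk %*% a)
  names(scores) <- rownames(M)
  new_selection_result("MMI", scores,
                       order_scores(scores, decreasing = FALSE),
                       higher_better = FALSE, extra = list(weights = a))
}

#' Truncate a ranking to the selected top fraction
#'
#' Marks the first `k` progenies of a strategy's ranking as selected. When a
#' fraction is given, `k = max(1, floor(fraction * N))`: selecting the best
#' 20% of 194 candidates keeps exactly 38.
#'
#' @param result A `selection_result`.
#' @param k Number of progenies to select, or
#' @param fraction Selected fraction in (0, 1].
#' @return The `selection_result` with `selected` (the first `k` of the
#'   ranking) and `k` filled in.
#' @export
select_top <- function(result, k = NULL, fraction = NULL) {
  stopifnot(inherits(result, "selection_result"))
  N <- length(result$ranking)
  if (is.null(k)) {
    if (is.null(fraction)) stop_recsel("give either k or fraction")
    if (!is_number(fraction) || fraction <= 0 || fraction > 1)
      stop_recsel("fraction must be in (0, 1]")
    k <- max(1L, as.integer(floor(fraction * N)))
  }
  k <- as.integer(k)
  if (k < 1L || k > N)
    stop_recsel("k = %d out of range (1..%d candidates)", k, N)
  result$k <- k
  result$selected <- result$ranking[seq_len(k)]
  result
}

#' Write a selection result to disk
#'
#' Writes scores and rankings as CSV (`strategy, progeny, score, rank,
#' selected`) and, when a selection was made, the selected identifiers as a
#' plain one-ID-per-line file next to it (suffix `_selected.txt`), the
#' interchange format of the coincidence analysis.
#'
#' @param result A `selection_result`.
#' @param csv_path CSV output path.
#' @return `csv_path`, invisibly.
#' @export
write_selection <- function(result, csv_path) {
  ord <- result$ranking
  tab <- data.frame(strategy = result$strategy, progeny = ord,
                    score = unname(result$scores[ord]),
                    rank = seq_along(ord),
                    selected = if (is.null(result$selected)) FALSE
                               else ord %in% result$selected,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(result$selected))
    writeLines(result$selected,
               sub("\\.csv$", "_selected.txt", csv_path))
  invisible(csv_path)
}

#' Read a one-ID-per-line selection file
#'
#' @param path Path to a plain-text file with one identifier per line.
#' @return Character vector of identifiers.
#' @export
read_selection_ids <- function(path) {
  ids <- readLines(path, encoding = "UTF-8")
  ids[nzchar(trimws(ids))]
}
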