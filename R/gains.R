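#' Inbreeding depression from S0 and S1 means
#'
#' The relative performance loss upon one generation of selfing:
#' `100 * (m0 - m1) / m0`, where `m0` is the non-inbred (S0) mean and `m1`
#' the selfed (S1) mean. Negative values (S1 above S0) are biologically
#' meaningful residual heterosis and are returned as-is, never clipped. The
#' statistic is scale-invariant: multiplying both means by any nonzero
#' constant leaves it unchanged.
#'
#' @param m0 S0 mean(s); must be nonzero.
#' @param m1 S1 mean(s); recycled against `m0`.
#' @return Inbreeding depression in percent, same length as the longer
#'   input.
#' @examples
#' inbreeding_depression(100, 60) # 40
#' inbreeding_depression(4000, 4400) # -10: heterotic S1
#' @export
inbreeding_depression <- function(m0, m1) {
  if (any(!is.finite(m0)) || any(!is.finite(m1)))
    stop_recsel("inbreeding_depression: means must be finite")
  if (any(m0 == 0))
    stop_recsel("inbreeding_depression undefined for m0 = 0")
  100 * (m0 - m1) / m0
}

#' Per-progeny inbreeding depression table from paired trials
#'
#' Applies [inbreeding_depression()] to the family means of a trait
#' observed in a half-sib (S0) trial and its paired selfed (S1) trial. At
#' `level = "rep"` (default) the S0 and S1 means of matching replicate
#' numbers are paired, giving one depression value per progeny and
#' replicate; this replication makes the family + residual mixed model of
#' the depression trait identifiable. At `level = "family"` a single value
#' per progeny is computed from the overall family means.
#'
#' @param s0,s1 `trial_table`s of the S0 and S1 generations.
#' @param trait Trait to depress (default `"GY"`).
#' @param level `"rep"` or `"family"`.
#' @param id_trait Name given to the derived trait (default `"ID"`).
#' @return A `trial_table`-shaped data frame (generation `"S0S1"`, trait
#'   `id_trait`) that can be appended to S0 rows for [estimate_PG()] or fed
#'   to [reml_fit()] with `random_terms = "family"`.
#' @export
id_table <- function(s0, s1, trait = "GY", level = c("rep", "family"),
                     id_trait = "ID") {
  level <- match.arg(level)
  a <- as.data.frame(s0)
  b <- as.data.frame(s1)
  a <- a[a$trait == trait & a$entry_type == "progeny", , drop = FALSE]
  b <- b[b$trait == trait & b$entry_type == "progeny", , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop_recsel("trait '%s' missing from one of the paired trials", trait)
  keys <- if (level == "rep") c("progeny_id", "rep") else "progeny_id"
  m0 <- stats::aggregate(a["value"], a[keys], mean)
  m1 <- stats::aggregate(b["value"], b[keys], mean)
  mm <- merge(m0, m1, by = keys, suffixes = c("_s0", "_s1"))
  if (!nrow(mm)) stop_recsel("no progenies shared between the S0 and S1 trials")
  grp <- unique(a[, c("progeny_id", "ancestry_group")])
  out <- data.frame(
    progeny_id = mm$progeny_id,
    entry_type = "progeny",
    generation = "S0S1",
    rep = if (level == "rep") mm$rep else 1L,
    block = 1L,
    plot = if (level == "rep") mm$rep else 1L,
    ancestry_group = grp$ancestry_group[match(mm$progeny_id, grp$progeny_id)],
    trait = id_trait,
    value = inbreeding_depression(mm$value_s0, mm$value_s1),
    stringsAsFactors = FALSE)
  out <- out[order(out$rep, out$progeny_id), ]
  rownames(out) <- NULL
  new_trial_table(out)
}

#' Predicted selection gain per trait for a selected set
#'
#' Computes, for every trait, the selected-set mean `Xs`, the candidate
#' (base) mean `X0`, and the predicted gain. In `"differential"` mode the
#' gain is the raw selection differential `Xs - X0`; in
#' `"heritability_adjusted"` mode (the default) it is the breeder's-equation
#' response `h2_family * (Xs - X0)`, using the family-mean heritabilities of
#' `params`. Percent gains are relative to `X0`. For minimize-traits the
#' gain is reported on the raw scale, so a favourable response is negative.
#'
#' For BLUP strategies pass the fit via `blup`: the gain for the modelled
#' trait is the mean of the selected progenies' BLUPs (already shrunken, so
#' no heritability adjustment applies), percent relative to the fit's base
#' mean.
#'
#' @param selected A `selection_result` with a selected set
#'   ([select_top()]), or a character vector of selected progeny ids.
#' @param means A `family_means` table of all candidates.
#' @param params Optional `genetic_params` (required for
#'   `"heritability_adjusted"`).
#' @param mode `"heritability_adjusted"` or `"differential"`.
#' @param blup Optional `blup_result`; adds/overrides the row for the
#'   modelled trait with the BLUP-based gain.
#' @param traits Traits to report (default all in `means`).
#' @param total `"absolute"` (default) sums absolute per-trait percent
#'   gains into the aggregate `total_pct`; `"signed"` sums them signed.
#' @return A data frame of class `gain_report` with columns `strategy`,
#'   `trait`, `Xs`, `X0`, `PG_abs`, `PG_pct`, `mode`; the aggregate percent
#'   gain is in `attr(, "total_pct")`.
#' @export
predicted_gain <- function(selected, means, params = NULL,
                           mode = c("heritability_adjusted", "differential"),
                           blup = NULL, traits = NULL,
                           total = c("absolute", "signed")) {
  mode <- match.arg(mode)
  total <- match.arg(total)
  if (inherits(selected, "selection_result")) {
    strategy <- selected$strategy
    ids <- selected$selected
    if (is.null(ids)) stop_recsel("run select_top() before predicted_gain()")
  } else {
    strategy <- "selection"
    ids <- as.character(selected)
  }
  if (!length(ids)) stop_recsel("selected set is empty")
  if (is.null(traits)) traits <- unique(means$trait)
  if (mode == "heritability_adjusted") {
    if (is.null(params)) stop_recsel("heritability_adjusted mode needs `params`")
    missing_h2 <- setdiff(traits, names(params$h2_family))
    if (length(missing_h2))
      stop_recsel("no heritability available for: %s", paste(missing_h2, collapse = ", "))
  }
  M <- means_matrix(means)
  bad <- setdiff(ids, rownames(M))
  if (length(bad))
    stop_recsel("selected ids missing from family means: %s",
                paste(utils::head(bad, 5), collapse = ", "))
  rows <- lapply(traits, function(tn) {
    xs <- mean(M[ids, tn], na.rm = TRUE)
    x0 <- mean(M[, tn], na.rm = TRUE)
    diff <- xs - x0
    pg <- if (mode == "heritability_adjusted") params$h2_family[[tn]] * diff else diff
    data.frame(strategy = strategy, trait = tn, Xs = xs, X0 = x0,
               PG_abs = pg,
               PG_pct = if (x0 != 0) 100 * pg / x0 else NA_real_,
               mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  if (!is.null(blup)) {
    stopifnot(inherits(blup, "blup_result"))
    sel_blups <- blup$blups[intersect(ids, names(blup$blups))]
    if (!length(sel_blups)) stop_recsel("selected ids missing from the BLUP fit")
    pg <- mean(sel_blups)
    row <- data.frame(strategy = strategy, trait = blup$trait,
                      Xs = blup$intercept + pg, X0 = blup$intercept,
                      PG_abs = pg,
                      PG_pct = if (blup$intercept != 0) 100 * pg / blup$intercept else NA_real_,
                      mode = "blup", stringsAsFactors = FALSE)
    out <- out[out$trait != blup$trait, , drop = FALSE]
    out <- rbind(out, row)
    out <- out[match(unique(c(traits, blup$trait)), out$trait), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total_pct") <- if (total == "absolute")
    sum(abs(out$PG_pct), na.rm = TRUE) else sum(out$PG_pct, na.rm = TRUE)
  class(out) <- c("gain_report", "data.frame")
  out
}

#' Realized gain of recombined populations
#'
#' Compares the trait means realized by recombined populations in a
#' follow-up trial against a base reference and, optionally, against the
#' predicted means, mirroring the predicted-versus-realized comparison of a
#' recurrent-selection validation trial.
#'
#' @param recombined A `trial_table` of the validation trial whose
#'   `progeny_id` column holds population identifiers.
#' @param base_reference Either a single number, a named numeric vector of
#'   base means per trait, or a `trial_table` (e.g. the check rows) whose
#'   per-trait means serve as the base.
#' @param predicted Optional data frame with columns `population`, `trait`,
#'   `predicted` giving predicted means (e.g. `Xs` from a [gain_report]).
#' @param populations Populations to report (default: all `progeny` rows).
#' @param traits Traits to report (default: all).
#' @return A data frame of class `realized_comparison`: `population`,
#'   `trait`, `realized_mean`, `base_mean`, `gain_abs`, `gain_pct`,
#'   `predicted_mean`, `difference` (realized - predicted).
#' @export
realized_gain <- function(recombined, base_reference, predicted = NULL,
                          populations = NULL, traits = NULL) {
  df <- as.data.frame(recombined)
  if (is.null(traits)) traits <- unique(df$trait)
  cand <- df[df$entry_type == "progeny" & df$trait %in% traits, , drop = FALSE]
  if (is.null(populations)) populations <- sort(unique(cand$progeny_id))
  absent <- setdiff(populations, unique(cand$progeny_id))
  if (length(absent))
    stop_recsel("population(s) absent from the trial: %s", paste(absent, collapse = ", "))

  if (inherits(base_reference, "data.frame")) {
    bdf <- as.data.frame(base_reference)
    bdf <- bdf[bdf$trait %in% traits, , drop = FALSE]
    base <- tapply(bdf$value, bdf$trait, mean)
  } else if (is.numeric(base_reference)) {
    base <- if (is.null(names(base_reference)))
      stats::setNames(rep(base_reference[1], length(traits)), traits)
    else base_reference
  } else stop_recsel("base_reference must be numeric or a trial table")

  rows <- list()
  for (pop in populations) for (tn in traits) {
    v <- cand$value[cand$progeny_id == pop & cand$trait == tn]
    if (!length(v)) next
    rm_ <- mean(v)
    b <- if (tn %in% names(base)) unname(base[tn]) else NA_real_
    pred <- NA_real_
    if (!is.null(predicted)) {
      hit <- predicted$population == pop & predicted$trait == tn
      if (any(hit)) pred <- predicted$predicted[which(hit)[1]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, trait = tn, realized_mean = rm_, base_mean = b,
      gain_abs = rm_ - b,
      gain_pct = if (!is.na(b) && b != 0) 100 * (rm_ - b) / b else NA_real_,
      predicted_mean = pred,
      difference = rm_ - pred,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("realized_comparison", "data.frame")
  out
}
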