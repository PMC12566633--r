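#' Mixed-model specification for a progeny trial
#'
#' Describes the linear mixed model fitted to one trait of one trial
#' generation: phenotype = fixed effects (intercept and, optionally,
#' ancestry group) + random replicate + random incomplete block within
#' replicate + random family (progeny) effect + residual. The family term is
#' always random (it carries the breeding values); the intercept is always
#' fixed.
#'
#' @param response_trait Trait identifier to model.
#' @param random_terms Subset of `c("rep", "block", "family")`; `"family"`
#'   must be included. Replicates are treated as random by default, with a
#'   fixed-replicate sensitivity fit available by dropping `"rep"` here and
#'   adding it to `fixed_terms`.
#' @param fixed_terms Subset of `c("intercept", "ancestry_group", "rep")`;
#'   `"intercept"` must be included.
#' @param convergence_tol Relative REML log-likelihood change declaring
#'   convergence (default `1e-8`).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response_trait,
                       random_terms = c("rep", "block", "family"),
                       fixed_terms = c("intercept", "ancestry_group"),
                       convergence_tol = 1e-8, max_iter = 500L) {
  stopifnot(is.character(response_trait), length(response_trait) == 1L)
  bad <- setdiff(random_terms, c("rep", "block", "family"))
  if (length(bad)) stop_recsel("unknown random term(s): %s", paste(bad, collapse = ", "))
  if (!"family" %in% random_terms)
    stop_recsel("the family effect must be a random term")
  bad <- setdiff(fixed_terms, c("intercept", "ancestry_group", "rep"))
  if (length(bad)) stop_recsel("unknown fixed term(s): %s", paste(bad, collapse = ", "))
  if (!"intercept" %in% fixed_terms) stop_recsel("the intercept must be fixed")
  if (any(c("rep") %in% random_terms & "rep" %in% fixed_terms))
    stop_recsel("'rep' cannot be both fixed and random")
  if (!is_number(convergence_tol) || convergence_tol <= 0)
    stop_recsel("convergence_tol must be > 0")
  structure(list(response_trait = response_trait,
                 random_terms = random_terms, fixed_terms = fixed_terms,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter)),
            class = "model_spec")
}

#' Build design structures for the trial mixed model
#'
#' Assembles the response vector and the fixed/random incidence matrices for
#' one trait of one trial generation. Checks are excluded (they are not
#' selection candidates). Rows are ordered by (rep, plot), which fixes the
#' row order of all matrices. Fixed effects use reference-level (treatment)
#' coding; the incomplete-block factor is block nested in replicate.
#'
#' @param trial A `trial_table` restricted to one generation.
#' @param spec A [model_spec()].
#' @return A list with `y`, `X` (fixed incidence), `Z` (named list of random
#'   incidence matrices), `progeny_levels`, `group_of` (ancestry group per
#'   progeny), and bookkeeping sizes.
#' @export
build_design <- function(trial, spec) {
  stopifnot(inherits(spec, "model_spec"))
  tr <- trial[trial$trait == spec$response_trait & trial$entry_type == "progeny", ,
              drop = FALSE]
  if (!nrow(tr))
    stop_recsel("trait '%s' not found; available traits: %s",
                spec$response_trait, paste(sort(unique(trial$trait)), collapse = ", "))
  gens <- unique(tr$generation)
  if (length(gens) > 1L)
    stop_recsel("trial contains %d generations (%s); restrict to one before fitting",
                length(gens), paste(gens, collapse = ", "))
  tr <- tr[order(tr$rep, tr$plot), , drop = FALSE]

  grp_tab <- unique(tr[, c("progeny_id", "ancestry_group")])
  if (anyDuplicated(grp_tab$progeny_id)) {
    dup <- grp_tab$progeny_id[duplicated(grp_tab$progeny_id)]
    stop_recsel("progeny in more than one ancestry group: %s",
                paste(unique(dup), collapse = ", "))
  }
  group_of <- stats::setNames(grp_tab$ancestry_group, grp_tab$progeny_id)

  y <- tr$value
  n <- length(y)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if ("ancestry_group" %in% spec$fixed_terms &&
      length(unique(tr$ancestry_group)) > 1L) {
    g <- factor(tr$ancestry_group)
    X <- cbind(X, stats::model.matrix(~g)[, -1, drop = FALSE])
  }
  if ("rep" %in% spec$fixed_terms && length(unique(tr$rep)) > 1L) {
    r <- factor(tr$rep)
    Xr <- stats::model.matrix(~r)[, -1, drop = FALSE]
    colnames(Xr) <- paste0("rep", levels(r)[-1])
    X <- cbind(X, Xr)
  }

  Z <- list()
  for (term in spec$random_terms) {
    f <- switch(term,
                family = factor(tr$progeny_id, levels = sort(unique(tr$progeny_id))),
                rep = factor(tr$rep),
                block = factor(paste(tr$rep, tr$block, sep = ":")))
    if (nlevels(f) < 2L)
      stop_recsel("random term '%s' has fewer than 2 levels", term)
    Zt <- stats::model.matrix(~ 0 + f)
    colnames(Zt) <- levels(f)
    Z[[term]] <- Zt
  }

  list(y = y, X = X, Z = Z,
       progeny_levels = levels(factor(tr$progeny_id, levels = sort(unique(tr$progeny_id)))),
       group_of = group_of, n = n, p = ncol(X),
       q = vapply(Z, ncol, 0L))
}

# One solve of Henderson's mixed-model equations at given variance
# components. M0 = W'W with W = [X, Z_1, ..., Z_K]; lambda_k = s2e/s2k is
# added to the diagonal of each random block. Returns solution, the inverse
# coefficient matrix, and log|M|.
solve_mme <- function(M0, Wty, p, q, s2, s2e) {
  M <- M0
  off <- p
  for (k in seq_along(q)) {
    idx <- off + seq_len(q[k])
    diag(M)[idx] <- diag(M)[idx] + s2e / s2[k]
    off <- off + q[k]
  }
  R <- chol(M)
  Cinv <- chol2inv(R)
  list(sol = drop(Cinv %*% Wty), Cinv = Cinv, logdetM = 2 * sum(log(diag(R))))
}

# Restricted log-likelihood from MME quantities:
# -2 logLR = (n-p-q)log s2e + sum_k q_k log s2k + log|M| + y'Py + const,
# with y'Py = (y'y - sol'W'y)/s2e.
reml_loglik <- function(n, p, q, s2, s2e, logdetM, ypy) {
  -0.5 * ((n - p - sum(q)) * log(s2e) + sum(q * log(s2)) + logdetM + ypy)
}

#' Fit the trial mixed model by EM-REML and extract BLUPs
#'
#' Estimates the variance components of the progeny-trial mixed model by
#' EM-REML (expectation–maximisation on Henderson's mixed-model equations)
#' and, at the converged components, solves the mixed-model equations for
#' the fixed effects and the BLUPs of family genotypic effects. Prediction
#' error variances come from the family block of the inverse coefficient
#' matrix. The reported intercept is the estimate for the reference
#' configuration averaged over ancestry-group effects weighted by group
#' sizes, so a single base mean is added to every BLUP to give predicted
#' genotypic values.
#'
#' EM-REML never leaves the parameter space and its restricted
#' log-likelihood is non-decreasing; the trace is stored in the result. If
#' `max_iter` is reached first, the result is returned with
#' `converged = FALSE` and a warning, never silently.
#'
#' @param trial A `trial_table` restricted to one generation.
#' @param spec A [model_spec()].
#' @param components Optional named numeric vector of known variance
#'   components (one entry per random term plus `"error"`). When supplied,
#'   no REML iteration is performed: the mixed-model equations are solved
#'   once at these values (useful for oracle comparisons and for BLUP at
#'   externally estimated components).
#' @return An object of class `blup_result`: `trait`, `intercept`, `blups`
#'   (named, mean approximately 0 in balanced designs), `genotypic_values`
#'   (`intercept + blup`), `pev`, `components` (named vector including
#'   `"error"`), `fixed` (fixed-effect estimates), `converged`, `n_iter`,
#'   `loglik_trace`, `n_obs`.
#' @export
reml_fit <- function(trial, spec, components = NULL) {
  d <- build_design(trial, spec)
  y <- d$y; n <- d$n; p <- d$p; q <- d$q
  vary <- stats::var(y)
  terms <- names(d$Z)

  degenerate <- function() {
    blups <- stats::setNames(rep(0, length(d$progeny_levels)), d$progeny_levels)
    comp <- stats::setNames(rep(0, length(terms) + 1L), c(terms, "error"))
    structure(list(trait = spec$response_trait, intercept = mean(y),
                   blups = blups, genotypic_values = blups + mean(y),
                   pev = blups, components = comp,
                   fixed = c("(Intercept)" = mean(y)),
                   converged = TRUE, n_iter = 0L, loglik_trace = numeric(),
                   n_obs = n, group_of = d$group_of),
              class = "blup_result")
  }
  if (!is.finite(vary) || vary < .Machine$double.eps * max(1, mean(y)^2)) {
    warn_recsel("response '%s' is constant: all components and BLUPs are 0",
                spec$response_trait)
    return(degenerate())
  }

  W <- cbind(d$X, do.call(cbind, d$Z))
  M0 <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y * y)
  floor_v <- 1e-10 * vary

  if (!is.null(components)) {
    missing <- setdiff(c(terms, "error"), names(components))
    if (length(missing))
      stop_recsel("components must name: %s", paste(c(terms, "error"), collapse = ", "))
    s2 <- pmax(as.numeric(components[terms]), floor_v)
    s2e <- max(as.numeric(components["error"]), floor_v)
    mm <- solve_mme(M0, Wty, p, q, s2, s2e)
    ypy <- (yty - sum(mm$sol * Wty)) / s2e
    ll <- reml_loglik(n, p, q, s2, s2e, mm$logdetM, ypy)
    fit <- list(sol = mm$sol, Cinv = mm$Cinv, s2 = s2, s2e = s2e,
                trace = ll, converged = TRUE, iter = 0L)
  } else {
    # EM-REML: start all components at an equal share of the phenotypic variance
    K <- length(terms)
    s2 <- stats::setNames(rep(vary / (K + 1), K), terms)
    s2e <- vary / (K + 1)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      mm <- solve_mme(M0, Wty, p, q, s2, s2e)
      ypy_num <- yty - sum(mm$sol * Wty)
      ll <- reml_loglik(n, p, q, s2, s2e, mm$logdetM, ypy_num / s2e)
      if (length(trace) && ll < ll_prev - (1e-6 * abs(ll_prev) + 1e-8))
        warn_recsel("EM-REML log-likelihood decreased at iteration %d", iter)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) / (abs(ll_prev) + 1e-10) < spec$convergence_tol) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      # EM updates
      off <- p
      s2_new <- s2
      for (k in seq_along(q)) {
        idx <- off + seq_len(q[k])
        u_k <- mm$sol[idx]
        trC <- sum(diag(mm$Cinv)[idx])
        s2_new[k] <- (sum(u_k^2) + s2e * trC) / q[k]
        off <- off + q[k]
      }
      s2e <- max(ypy_num / (n - p), floor_v)
      s2 <- pmax(s2_new, floor_v)
      if (iter >= spec$max_iter) break
    }
    if (!converged)
      warn_recsel("EM-REML did not converge for '%s' in %d iterations",
                  spec$response_trait, spec$max_iter)
    mm <- solve_mme(M0, Wty, p, q, s2, s2e)
    fit <- list(sol = mm$sol, Cinv = mm$Cinv, s2 = s2, s2e = s2e,
                trace = trace, converged = converged, iter = iter)
  }

  sol <- fit$sol
  beta <- stats::setNames(sol[seq_len(p)], colnames(d$X))
  fam_k <- match("family", terms)
  fam_off <- p + if (fam_k > 1) sum(q[seq_len(fam_k - 1L)]) else 0L
  fam_idx <- fam_off + seq_len(q[fam_k])
  blups <- stats::setNames(sol[fam_idx], d$progeny_levels)
  pev <- stats::setNames(pmax(diag(fit$Cinv)[fam_idx] * fit$s2e, 0), d$progeny_levels)

  zero_fam <- fit$s2[fam_k] <= 2 * floor_v
  if (zero_fam) {
    warn_recsel("family variance estimated at zero for '%s': all BLUPs are 0",
                spec$response_trait)
    blups[] <- 0
  }

  # single base mean: intercept + group effects averaged with group sizes
  intercept <- unname(beta[1])
  grp_cols <- grep("^g", names(beta))
  if (length(grp_cols)) {
    tab <- table(d$group_of)
    wts <- tab / sum(tab)
    lev <- sort(names(tab))
    eff <- stats::setNames(rep(0, length(lev)), lev)
    eff[sub("^g", "", names(beta)[grp_cols])] <- beta[grp_cols]
    intercept <- unname(beta[1]) + sum(wts[lev] * eff[lev])
  }

  comp <- stats::setNames(c(fit$s2, fit$s2e), c(terms, "error"))
  if (zero_fam) comp["family"] <- 0

  structure(list(trait = spec$response_trait, intercept = intercept,
                 blups = blups, genotypic_values = intercept + blups,
                 pev = pev, components = comp, fixed = beta,
                 converged = fit$converged, n_iter = fit$iter,
                 loglik_trace = fit$trace, n_obs = n,
                 group_of = d$group_of),
            class = "blup_result")
}

#' @export
print.blup_result <- function(x, ...) {
  cat("REML/BLUP fit for trait", x$trait, "\n")
  cat(sprintf("  n = %d, intercept (base mean) = %.4g\n", x$n_obs, x$intercept))
  cat("  variance components:\n")
  print(round(x$components, 6))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged, x$n_iter))
  invisible(x)
}

#' Predicted genotypic values from a BLUP fit
#'
#' Returns the per-progeny table of BLUPs and predicted genotypic values
#' (base mean + BLUP), sorted best-first: descending for a maximize trait
#' (grain yield), ascending for a minimize trait (inbreeding depression).
#' Ties are broken by progeny identifier.
#'
#' @param result A `blup_result` from [reml_fit()].
#' @param direction `"maximize"` or `"minimize"`.
#' @return A data frame with columns `progeny`, `blup`, `genotypic_value`,
#'   `pev`.
#' @export
predict_genotypic_values <- function(result, direction = c("maximize", "minimize")) {
  stopifnot(inherits(result, "blup_result"))
  direction <- match.arg(direction)
  ord <- order_scores(result$genotypic_values, decreasing = direction == "maximize")
  data.frame(progeny = ord,
             blup = unname(result$blups[ord]),
             genotypic_value = unname(result$genotypic_values[ord]),
             pev = unname(result$pev[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Selection ranking from a BLUP fit
#'
#' Wraps a [reml_fit()] result as a selection strategy ranked by predicted
#' genotypic value, ready for [select_top()] and the coincidence analysis.
#'
#' @param result A `blup_result`.
#' @param strategy Strategy label (e.g. `"BLUP_GY"`, `"BLUP_ID"`).
#' @param direction `"maximize"` or `"minimize"`.
#' @return A `selection_result` (see [base_index()]).
#' @export
blup_selection <- function(result, strategy, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  higher <- direction == "maximize"
  scores <- result$genotypic_values
  new_selection_result(strategy = strategy, scores = scores,
                       ranking = order_scores(scores, decreasing = higher),
                       higher_better = higher)
}

#' Write a BLUP fit to disk
#'
#' Writes the per-progeny results as CSV (`progeny, blup, genotypic_value,
#' pev`) and the fit summary (components, log-likelihood trace, convergence)
#' as JSON.
#'
#' @param result A `blup_result`.
#' @param csv_path CSV output path.
#' @param json_path Optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_blup <- function(result, csv_path, json_path = NULL) {
  tab <- predict_genotypic_values(result)
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(trait = result$trait, intercept = result$intercept,
           components = as.list(result$components),
           loglik_trace = result$loglik_trace,
           converged = result$converged, n_iter = result$n_iter,
           n_obs = result$n_obs),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
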